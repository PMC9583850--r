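# ggplot2 views of the pipeline's result objects.

#' @importFrom ggplot2 ggplot aes geom_point geom_histogram geom_line
#'   geom_vline geom_hline geom_abline facet_wrap labs theme_bw autoplot
#'   scale_fill_manual scale_colour_manual geom_bin2d
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-strain histograms of replicate mean GFP with the threshold line
#'
#' One panel per strain, replicate mean log10 GFP on the x axis, coloured
#' by intended output (low = blue, high = orange), with the calibrated
#' threshold as a dashed line — the grid view in which whole-well failures
#' appear as replicate-level bimodality.
#'
#' @param classified output of [classify_replicates()].
#' @param threshold a `threshold_result` or numeric (log10 a.u.).
#' @param bins histogram bins.
#' @return A ggplot object.
#' @export
plot_strain_histograms <- function(classified, threshold, bins = 30) {
  t <- if (inherits(threshold, "threshold_result")) threshold$threshold else threshold
  dat <- filter(classified, .data$strain != "WT")
  ggplot(dat, aes(x = .data$mean_log_gfp,
                  fill = factor(.data$expected_output))) +
    geom_histogram(bins = bins) +
    geom_vline(xintercept = t, linetype = "dashed", colour = "red") +
    facet_wrap(~strain, ncol = 4) +
    scale_fill_manual(values = c("0" = "#4477AA", "1" = "#EE7733"),
                      name = "intended output") +
    labs(x = "mean log10 GFP per replicate (a.u.)", y = "replicates") +
    theme_bw()
}

#' Scatter-cluster heatmap view
#'
#' Binned log-log scatter density, faceted by cluster, mirroring the
#' per-cluster heatmap panels used to display the bimodal scatter
#' structure.
#'
#' @param object a `scatter_clusters` object.
#' @param bins bins per axis.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot scatter_clusters
#' @export
autoplot.scatter_clusters <- function(object, bins = 60, ...) {
  ggplot(object$data, aes(x = .data$log_fsc, y = .data$log_ssc)) +
    geom_bin2d(bins = bins) +
    facet_wrap(~cluster, labeller = ggplot2::label_both) +
    labs(x = "log10 FSC_A (a.u.)", y = "log10 SSC_A (a.u.)") +
    theme_bw()
}

#' Control separation view of a calibrated threshold
#'
#' @param object a `threshold_result`.
#' @param summaries the well summaries the threshold was calibrated from.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot threshold_result
#' @export
autoplot.threshold_result <- function(object, summaries, ...) {
  ctl <- filter(summaries, !is.na(.data$control_role), .data$retained)
  ggplot(ctl, aes(x = .data$mean_log_gfp, fill = .data$control_role)) +
    geom_histogram(bins = 40, alpha = 0.8, position = "identity") +
    geom_vline(xintercept = object$threshold, linetype = "dashed",
               colour = "red") +
    scale_fill_manual(values = c(negative = "#4477AA", positive = "#EE7733")) +
    labs(x = "control well mean log10 GFP (a.u.)", y = "wells") +
    theme_bw()
}

#' Per-cluster GFP density curves
#'
#' @param object a `cluster_gfp` object from [compare_cluster_gfp()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot cluster_gfp
#' @export
autoplot.cluster_gfp <- function(object, ...) {
  ggplot(object$densities,
         aes(x = .data$log_gfp, y = .data$density,
             colour = factor(.data$cluster))) +
    geom_line() +
    scale_colour_manual(values = c("1" = "#CC3311", "2" = "#0077BB"),
                        name = "cluster") +
    labs(x = "log10 GFP (a.u.)", y = "kernel density") +
    theme_bw()
}

#' Initial vs final OD scatter
#'
#' @param records plate-reader tibble with `initial_od`, `final_od`.
#' @return A ggplot object.
#' @export
plot_od_growth <- function(records) {
  ggplot(records, aes(x = .data$initial_od, y = .data$final_od)) +
    geom_point(alpha = 0.4) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    labs(x = "initial OD (post-recovery)", y = "final OD") +
    theme_bw()
}

#' Bulk GFP vs OD-scaled per-cell GFP, with outliers marked
#'
#' @param object an `fc_pr_consistency` object.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot fc_pr_consistency
#' @export
autoplot.fc_pr_consistency <- function(object, ...) {
  ggplot(object$wells, aes(x = .data$predictor, y = .data$bulk_gfp,
                           colour = .data$outlier)) +
    geom_point(alpha = 0.6) +
    geom_abline(slope = object$slope, intercept = object$intercept,
                linetype = "dashed") +
    scale_colour_manual(values = c("FALSE" = "grey30", "TRUE" = "#CC3311")) +
    labs(x = "final OD x per-cell GFP (linear a.u.)",
         y = "plate-reader bulk GFP (a.u.)") +
    theme_bw()
}
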