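# End-to-end orchestration: simulate or ingest -> gate -> calibrate ->
# score -> scatter -> plate reader -> sequence verification, with one
# seed fanning out to per-stage substreams and reproducible outputs.

#' Campaign analysis configuration
#'
#' Bundles the stage configurations for [run_campaign()]. Exactly one data
#' source is active: a simulation configuration (the default), or a
#' pre-built campaign object/loaded dataset passed to [run_campaign()]
#' directly.
#'
#' @param simulation a [sim_config()].
#' @param gate a [gate_config()].
#' @param excluded_plates explicit plate exclusion list (the primary
#'   outlier-plate mechanism).
#' @param outlier_heuristic run [flag_outlier_plates()] and exclude its
#'   plates too; off by default.
#' @param statistic per-well statistic thresholded for correctness; see
#'   [classify_replicates()].
#' @param run_dnaseq run the sequence-verification stage when reads are
#'   available.
#' @param output_dir optional directory for TSV/JSON outputs.
#' @return An object of class `campaign_config`.
#' @export
campaign_config <- function(simulation = sim_config(),
                            gate = gate_config(),
                            excluded_plates = NULL,
                            outlier_heuristic = FALSE,
                            statistic = "mean_of_log",
                            run_dnaseq = TRUE,
                            output_dir = NULL) {
  structure(
    list(simulation = simulation, gate = gate,
         excluded_plates = excluded_plates,
         outlier_heuristic = outlier_heuristic,
         statistic = statistic, run_dnaseq = run_dnaseq,
         output_dir = output_dir),
    class = "campaign_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic (or supplied) campaign: well
#' gating and aggregation, plate exclusions, control-based threshold
#' calibration, replicate/strain/circuit correctness scoring (pooled and
#' standard-conditions groupings), per-control-strain scatter clustering
#' with GFP comparison, plate-reader growth and consistency checks, and —
#' when reads are present — gRNA design verification. Identical
#' configuration and seed give identical results; the summary written to
#' `output_dir` embeds the seed and a configuration hash.
#'
#' @param config a [campaign_config()].
#' @param campaign optionally, an existing [simulate_campaign()] object to
#'   analyse instead of simulating from `config$simulation`.
#' @return An object of class `campaign_report`: list with elements
#'   `well_summaries`, `threshold`, `classified`, `strain_scores`,
#'   `circuit_scores`, `summary_all`, `summary_standard`, `scatter` (per
#'   control strain), `plate_reader` (correlations + consistency),
#'   `dnaseq` (or `NULL`), `excluded_plates`, `seed`, `config_hash`.
#' @export
run_campaign <- function(config = campaign_config(), campaign = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  if (is.null(campaign)) {
    campaign <- simulate_campaign(config$simulation)
  }
  seed <- campaign$seed %||% config$simulation$seed

  summaries <- summarize_wells(campaign$events, config$gate,
                               layout = campaign$layout)
  excluded <- config$excluded_plates %||% character(0)
  if (isTRUE(config$outlier_heuristic)) {
    excluded <- union(excluded, flag_outlier_plates(summaries))
  }
  summaries_kept <- apply_plate_exclusions(summaries, excluded)

  threshold <- gfp_threshold(summaries_kept)

  classified <- classify_replicates(
    filter(summaries_kept, .data$retained),
    threshold, statistic = config$statistic
  )
  summary_all <- summarize_campaign_correctness(classified, "all_conditions")
  summary_std <- summarize_campaign_correctness(classified, "standard_conditions")

  # scatter bimodality on each control strain separately
  ctl_wells <- filter(campaign$layout, !is.na(.data$control_role))
  scatter <- purrr::map(
    stats::setNames(unique(ctl_wells$strain), unique(ctl_wells$strain)),
    function(s) {
      ev <- filter(campaign$events,
                   .data$well_id %in% ctl_wells$well_id[ctl_wells$strain == s])
      ev <- apply_gate(ev, config$gate)
      cl <- cluster_scatter(ev, seed = substream_seed(seed, paste0("kmeans/", s)))
      list(clusters = cl, gfp = compare_cluster_gfp(cl))
    }
  )

  pr <- campaign$plate_reader
  plate_reader <- if (!is.null(pr)) {
    pr_kept <- filter(pr, !.data$plate %in% excluded)
    list(
      records = pr_kept,
      rho_overall = od_growth_correlation(pr_kept),
      rho_by_strain = od_growth_correlation(pr_kept, group_by = "strain"),
      rho_by_hours = od_growth_correlation(pr_kept, group_by = "overnight_hours"),
      consistency = fc_pr_consistency(pr_kept, filter(summaries_kept, .data$retained))
    )
  }

  dnaseq <- NULL
  if (isTRUE(config$run_dnaseq) && !is.null(campaign$reads) &&
        length(campaign$reads) > 0) {
    lib <- campaign$grna_library
    design <- build_design_matrix(campaign$config$strains %||% strain_panel(), lib)
    results <- build_results_matrix(campaign$reads, lib)
    dnaseq <- list(
      design = design, results = results,
      anomalies = find_anomalies(design, results),
      coverage = coverage_estimate(campaign$reads,
                                   campaign$config$reads$genome_size %||% 1.2e7)
    )
  }

  report <- structure(
    list(
      well_summaries = summaries,
      excluded_plates = excluded,
      threshold = threshold,
      classified = classified,
      strain_scores = summary_all$strain_scores,
      circuit_scores = summary_all$circuit_scores,
      summary_all = summary_all$counts,
      summary_standard = summary_std$counts,
      scatter = scatter,
      plate_reader = plate_reader,
      dnaseq = dnaseq,
      seed = seed,
      config_hash = rlang::hash(list(unclass(config)[setdiff(names(config), "output_dir")], seed))
    ),
    class = "campaign_report"
  )
  if (!is.null(config$output_dir)) {
    write_report(report, config$output_dir)
  }
  report
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("<campaign_report> seed ", x$seed, ", config ", x$config_hash, "\n", sep = "")
  cat(sprintf("  %d wells summarized, %d retained; threshold %.3f log10 a.u. (cost %.4g)\n",
              nrow(x$well_summaries), sum(x$well_summaries$retained),
              x$threshold$threshold, x$threshold$cost))
  cat(sprintf("  strains: %d green / %d gray of %d (all conditions)\n",
              x$summary_all$n_green, x$summary_all$n_gray, x$summary_all$n_strains))
  if (!is.null(x$dnaseq)) {
    cat(sprintf("  dnaseq: %d anomalous cell(s)\n", x$dnaseq$anomalies$n_anomalies))
  }
  invisible(x)
}

#' Tidy / glance methods for a campaign report
#'
#' @param x a `campaign_report`.
#' @param ... unused.
#' @return `tidy()`: the strain-score table; `glance()`: one row of
#'   headline numbers (threshold, cost, retained wells, green/gray counts,
#'   anomaly count).
#' @method tidy campaign_report
#' @export
tidy.campaign_report <- function(x, ...) x$strain_scores

#' @rdname tidy.campaign_report
#' @method glance campaign_report
#' @export
glance.campaign_report <- function(x, ...) {
  tibble(
    threshold = x$threshold$threshold,
    threshold_cost = x$threshold$cost,
    n_wells = nrow(x$well_summaries),
    n_retained = sum(x$well_summaries$retained),
    n_green = x$summary_all$n_green,
    n_gray = x$summary_all$n_gray,
    n_anomalies = if (is.null(x$dnaseq)) NA_integer_ else x$dnaseq$anomalies$n_anomalies,
    seed = x$seed
  )
}

# Tables first (headless runs must succeed without a display); figures are
# left to the user via the plot_*/autoplot functions.
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- paste0("# gatescore seed=", report$seed,
                  " config=", report$config_hash)
  wt <- function(x, f) {
    path <- file.path(dir, f)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(
      x, path, sep = "\t", row.names = FALSE, quote = FALSE, append = TRUE
    ))
  }
  ws <- report$well_summaries
  wt(ws[setdiff(names(ws), "grnas")], "well_summaries.tsv")
  wt(report$strain_scores, "strain_scores.tsv")
  wt(report$circuit_scores, "circuit_scores.tsv")
  if (!is.null(report$dnaseq)) {
    wt(report$dnaseq$anomalies$cells, "dnaseq_anomalies.tsv")
  }
  scatter_tbl <- purrr::imap_dfr(report$scatter, function(s, nm) {
    mutate(tidy(s$clusters), strain = nm, .before = 1)
  })
  wt(scatter_tbl, "scatter_clusters.tsv")
  jsonlite::write_json(
    list(
      seed = report$seed,
      config_hash = report$config_hash,
      threshold = tidy(report$threshold),
      summary_all = report$summary_all,
      summary_standard = report$summary_standard,
      circuit_scores = report$circuit_scores,
      excluded_plates = report$excluded_plates
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(dir)
}
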