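# Plate-reader analyses: the protocol's dilution-volume computation, OD
# growth relationships, and the cross-modality consistency check between
# plate-reader bulk GFP and per-cell cytometer GFP.

#' Dilution plan to reach a target OD
#'
#' Computes the growth-medium volume to add to a culture so the mixture
#' starts at the target optical density. With
#' `fold = measured_od / target_od`, the culture is mixed culture:total at
#' 1:`fold` — one part culture brought up to `fold` parts total — so
#' `media_volume = culture_volume * (fold - 1)`. (Reading the ratio as
#' culture:media instead would land at `measured_od * fold/(fold+1)^(-1)`,
#' slightly off target; only the culture:total reading reproduces
#' OD 1.0 -> 0.01 exactly at 1:100.)
#'
#' @param measured_od pre-dilution OD from the overnight recovery plate.
#' @param target_od intended starting OD of the growth phase.
#' @param culture_volume volume of culture transferred, microliters.
#' @return One-row tibble: `measured_od`, `target_od`, `culture_volume`,
#'   `media_volume` (microliters), `fold` (dilution factor, culture:total).
#' @examples
#' dilution_plan(1.0, 0.01, 10) # 1:100, add 990 ul media to 10 ul culture
#' @export
dilution_plan <- function(measured_od, target_od, culture_volume = 10) {
  stopifnot(measured_od > 0, culture_volume > 0, target_od > 0)
  if (any(target_od > measured_od)) {
    abort("target_od exceeds measured_od: cannot concentrate by dilution",
          class = "gatescore_dilution_error")
  }
  fold <- measured_od / target_od
  tibble(
    measured_od = measured_od, target_od = target_od,
    culture_volume = culture_volume,
    media_volume = culture_volume * (fold - 1),
    fold = fold
  )
}

#' Correlation between initial and final OD
#'
#' Pearson correlation of post-recovery (initial) versus final OD, overall
#' or per group — the basic check on whether replicates grew. Groups with
#' fewer than `min_n` records, or with a constant vector (undefined
#' correlation), are flagged rather than reported as numbers. Negative
#' correlations are flagged too: they mark pathological batches in which
#' denser starting cultures systematically grew *less*.
#'
#' @param records tibble with `initial_od`, `final_od` and any grouping
#'   columns.
#' @param group_by character vector of grouping column names (e.g.
#'   `"strain"` or `c("overnight_hours")`), or `NULL` for a pooled estimate.
#' @param min_n minimum records per group.
#' @return Tibble: grouping columns, `n`, `rho`, `flag` (`"ok"`,
#'   `"too_few"`, `"undefined"` or `"negative"`).
#' @export
od_growth_correlation <- function(records, group_by = NULL, min_n = 3L) {
  stopifnot(all(c("initial_od", "final_od") %in% names(records)))
  grouped <- if (is.null(group_by)) {
    mutate(records, .group = "all") |> group_by(.data$.group)
  } else {
    group_by(records, across(dplyr::all_of(group_by)))
  }
  out <- grouped |>
    summarise(
      n = n(),
      rho = if (n() < min_n || stats::sd(.data$initial_od) == 0 ||
                  stats::sd(.data$final_od) == 0) NA_real_ else {
        stats::cor(.data$initial_od, .data$final_od)
      },
      .groups = "drop"
    ) |>
    mutate(flag = dplyr::case_when(
      .data$n < min_n ~ "too_few",
      is.na(.data$rho) ~ "undefined",
      .data$rho < 0 ~ "negative",
      TRUE ~ "ok"
    ))
  if (is.null(group_by)) out <- select(out, -".group")
  out
}

#' Consistency between plate-reader bulk GFP and cytometer per-cell GFP
#'
#' Bulk fluorescence read by the plate reader should agree with per-cell
#' GFP from the cytometer scaled by culture density: the check regresses
#' `bulk_gfp` on `final_od * 10^mean_log_gfp` (per-cell GFP re-expressed
#' on the linear a.u. scale, where fluorescence is additive over cells).
#' Disagreement flags a measurement problem in one modality. Wells whose
#' residual exceeds `k` residual SDs are flagged as outliers.
#'
#' @param records plate-reader tibble with `well_id`, `final_od`,
#'   `bulk_gfp`.
#' @param summaries well summaries with `well_id`, `mean_log_gfp`.
#' @param k outlier flagging multiple of the residual SD.
#' @return List of class `fc_pr_consistency`: `fit` (the `lm`), `slope`,
#'   `intercept`, `r`, `wells` (per-well predictor, residual, `outlier`
#'   flag), `n`.
#' @export
fc_pr_consistency <- function(records, summaries, k = 3) {
  stopifnot(all(c("well_id", "final_od", "bulk_gfp") %in% names(records)),
            all(c("well_id", "mean_log_gfp") %in% names(summaries)))
  matched <- inner_join(
    select(records, "well_id", "final_od", "bulk_gfp"),
    select(summaries, "well_id", "mean_log_gfp"),
    by = "well_id"
  ) |>
    filter(is.finite(.data$mean_log_gfp))
  if (nrow(matched) == 0) {
    abort("no wells matched between plate-reader records and FC summaries",
          class = "gatescore_consistency_error")
  }
  matched <- mutate(matched,
                    predictor = .data$final_od * 10^.data$mean_log_gfp)
  fit <- stats::lm(bulk_gfp ~ predictor, data = matched)
  res <- stats::residuals(fit)
  sd_res <- stats::sd(res)
  # an essentially exact fit has no outliers: guard against flagging
  # numerically-zero residuals
  meaningful <- sd_res > 1e-8 * max(abs(matched$bulk_gfp), 1e-300)
  matched$residual <- res
  matched$outlier <- if (meaningful) abs(res) > k * sd_res else rep(FALSE, length(res))
  structure(
    list(
      fit = fit,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = if (stats::sd(matched$predictor) == 0 ||
                stats::sd(matched$bulk_gfp) == 0) NA_real_ else {
        stats::cor(matched$predictor, matched$bulk_gfp)
      },
      wells = matched,
      n = nrow(matched)
    ),
    class = "fc_pr_consistency"
  )
}

#' @export
print.fc_pr_consistency <- function(x, ...) {
  cat(sprintf(
    "<fc_pr_consistency> n = %d wells\n  bulk_gfp = %.4g + %.4g * (final_od x per-cell GFP), r = %.4f\n  %d outlier well(s) flagged\n",
    x$n, x$intercept, x$slope, x$r, sum(x$wells$outlier)))
  invisible(x)
}

#' Tidy / glance methods for the FC vs plate-reader consistency fit
#'
#' @param x an `fc_pr_consistency` object.
#' @param ... unused.
#' @return `tidy()`: the per-well table with residuals and outlier flags;
#'   `glance()`: one row with `slope`, `intercept`, `r`, `n`, `n_outliers`.
#' @method tidy fc_pr_consistency
#' @export
tidy.fc_pr_consistency <- function(x, ...) x$wells

#' @rdname tidy.fc_pr_consistency
#' @method glance fc_pr_consistency
#' @export
glance.fc_pr_consistency <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r,
         n = x$n, n_outliers = sum(x$wells$outlier))
}

#' Read a plate-reader table
#'
#' TSV or CSV with at least `well_id`, `initial_od`, `final_od`,
#' `bulk_gfp` columns, as written by [write_campaign()].
#'
#' @param path file path; delimiter inferred from the extension.
#' @param blank optional blank reading subtracted from both OD columns.
#' @return A tibble.
#' @export
read_plate_reader <- function(path, blank = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- as_tibble(utils::read.table(path, sep = sep, header = TRUE,
                                    stringsAsFactors = FALSE))
  if (!is.null(blank)) {
    df <- mutate(df,
                 initial_od = pmax(.data$initial_od - blank, 0),
                 final_od = pmax(.data$final_od - blank, 0))
  }
  df
}
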