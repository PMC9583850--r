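# Scatter gating: remove debris and saturated events, aggregate wells,
# and apply plate-level exclusions.

#' Gating configuration
#'
#' Events are retained when both scatter channels fall inside
#' `[fsc_min, scatter_max]` x `[ssc_min, scatter_max]`. The upper cut
#' (default 900,000 a.u.) removes events near the instrument ceiling of
#' 1,048,575 a.u., where measurements saturate; the lower cuts remove
#' debris. The instrument gives only arbitrary units, so the lower cuts
#' are deliberately configurable — the defaults (10,000 a.u.) are
#' conservative fixture values suited to the synthetic generator's scale,
#' not universal constants. Wells keeping fewer than `min_gated_events`
#' events (default 10,000) are dropped from analysis.
#'
#' @param fsc_min,ssc_min lower scatter cuts in a.u.
#' @param scatter_max upper scatter cut in a.u. applied to both channels.
#' @param min_gated_events minimum gated events for a well to be retained.
#' @param gfp_floor GFP values below this (a.u.) are clamped before the
#'   log10 transform, guarding against non-positive compensated values.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(fsc_min = 10000, ssc_min = 10000,
                        scatter_max = 900000,
                        min_gated_events = 10000,
                        gfp_floor = 1) {
  stopifnot(fsc_min >= 0, ssc_min >= 0,
            fsc_min < scatter_max, ssc_min < scatter_max,
            min_gated_events > 0, gfp_floor > 0)
  structure(
    list(fsc_min = fsc_min, ssc_min = ssc_min, scatter_max = scatter_max,
         min_gated_events = min_gated_events, gfp_floor = gfp_floor),
    class = "gate_config"
  )
}

#' Gate flow-cytometry events on forward and side scatter
#'
#' Retains exactly the events with `fsc_min <= FSC_A <= scatter_max` and
#' `ssc_min <= SSC_A <= scatter_max`, preserving event order. Gating is a
#' pure row filter: it is idempotent, and tightening any bound can only
#' shrink the result.
#'
#' @param events tibble with columns `fsc_a`, `ssc_a` (a.u.); extra columns
#'   (e.g. `gfp`, `well_id`) pass through untouched.
#' @param cfg a [gate_config()].
#' @return The gated subset of `events`, same columns.
#' @examples
#' ev <- tibble::tibble(fsc_a = c(5e4, 95e4), ssc_a = c(5e4, 5e4), gfp = 1:2)
#' apply_gate(ev, gate_config())  # the 950,000 a.u. event is removed
#' @export
apply_gate <- function(events, cfg = gate_config()) {
  stopifnot(all(c("fsc_a", "ssc_a") %in% names(events)))
  keep <- events$fsc_a >= cfg$fsc_min & events$fsc_a <= cfg$scatter_max &
    events$ssc_a >= cfg$ssc_min & events$ssc_a <= cfg$scatter_max
  events[keep, , drop = FALSE]
}

#' Summarize gated events per well
#'
#' Aggregates each well to the statistics the correctness analysis runs
#' on: gated event count, and mean and SD of log10 GFP (GFP clamped to
#' `gfp_floor` before the log). A well is `retained` only if it keeps at
#' least `min_gated_events` gated events. Analysis is done at the
#' replicate/well level throughout: wells of the same strain can differ
#' wholesale, so pooling cells across replicates would confound results.
#'
#' @param events *raw* event tibble with columns `well_id`, `fsc_a`,
#'   `ssc_a`, `gfp`; gating is applied internally so raw and gated counts
#'   can both be reported.
#' @param cfg a [gate_config()].
#' @param layout optional well metadata (tibble keyed by `well_id`) joined
#'   onto the summaries.
#' @return A tibble with one row per well: `well_id`, `n_raw`, `n_gated`,
#'   `mean_log_gfp`, `sd_log_gfp`, `retained`, plus any layout columns.
#'   Wells with no gated events get `NA` means and `retained = FALSE`.
#' @export
summarize_wells <- function(events, cfg = gate_config(), layout = NULL) {
  stopifnot(all(c("well_id", "fsc_a", "ssc_a", "gfp") %in% names(events)))
  raw_counts <- events |> count(.data$well_id, name = "n_raw")
  gated <- apply_gate(events, cfg)
  summ <- gated |>
    group_by(.data$well_id) |>
    summarise(
      n_gated = n(),
      mean_log_gfp = mean(log10(pmax(.data$gfp, cfg$gfp_floor))),
      sd_log_gfp = stats::sd(log10(pmax(.data$gfp, cfg$gfp_floor))),
      .groups = "drop"
    )
  out <- raw_counts |>
    left_join(summ, by = "well_id") |>
    mutate(
      n_gated = dplyr::coalesce(.data$n_gated, 0L),
      retained = .data$n_gated >= cfg$min_gated_events
    )
  if (!is.null(layout)) {
    meta <- distinct(layout, .data$well_id, .keep_all = TRUE)
    meta <- meta[setdiff(names(meta), c("grnas"))]
    out <- left_join(out, meta, by = "well_id")
  }
  out
}

#' Remove wells on excluded plates
#'
#' Campaigns occasionally produce whole plates with abnormal behaviour;
#' the primary mechanism for handling them is an explicit curated
#' exclusion list. Unknown plate identifiers raise a warning and are
#' ignored.
#'
#' @param summaries well-summary tibble with a `plate` column.
#' @param excluded_plates vector of plate identifiers to drop.
#' @return `summaries` without wells on excluded plates.
#' @seealso [flag_outlier_plates()] for an optional data-driven heuristic.
#' @export
apply_plate_exclusions <- function(summaries, excluded_plates = NULL) {
  if (is.null(excluded_plates) || length(excluded_plates) == 0) {
    return(summaries)
  }
  stopifnot("plate" %in% names(summaries))
  unknown <- setdiff(excluded_plates, unique(summaries$plate))
  if (length(unknown) > 0) {
    warn(paste0("unknown plate id(s) in exclusion list, ignored: ",
                paste(unknown, collapse = ", ")))
  }
  filter(summaries, !.data$plate %in% excluded_plates)
}

#' Flag plates whose positive controls under-fluoresce (optional heuristic)
#'
#' A plate is flagged when the median `mean_log_gfp` of its positive
#' control (NOR00) wells falls below `min_pos_median`. This is an optional
#' screening aid, off by default in [run_campaign()]: curated exclusion
#' lists are the primary mechanism.
#'
#' @param summaries well-summary tibble with `plate`, `control_role`,
#'   `mean_log_gfp` columns.
#' @param min_pos_median flagging threshold in log10 a.u.
#' @return Vector of flagged plate identifiers (possibly empty).
#' @export
flag_outlier_plates <- function(summaries, min_pos_median = 3) {
  stopifnot(all(c("plate", "control_role", "mean_log_gfp") %in% names(summaries)))
  summaries |>
    filter(.data$control_role %in% "positive", .data$retained) |>
    group_by(.data$plate) |>
    summarise(pos_median = stats::median(.data$mean_log_gfp), .groups = "drop") |>
    filter(.data$pos_median < min_pos_median) |>
    pull(.data$plate)
}

#' Read per-well event CSV files
#'
#' Reads the CSV dialect written by [write_campaign()] (columns `fsc_a`,
#' `ssc_a`, `gfp`, optionally `well_id`); channel column names are
#' configurable for files exported from other software.
#'
#' @param paths CSV file paths; each file is one well. When a file lacks a
#'   `well_id` column, the file name (sans extension) is used.
#' @param channels named character vector mapping the standard names
#'   `fsc_a`, `ssc_a`, `gfp` to the column names found in the files.
#' @return One tibble of events with a `well_id` column.
#' @export
read_event_csv <- function(paths,
                           channels = c(fsc_a = "fsc_a", ssc_a = "ssc_a",
                                        gfp = "gfp")) {
  purrr::map_dfr(paths, function(p) {
    df <- as_tibble(utils::read.csv(p, check.names = FALSE))
    missing <- setdiff(unname(channels), names(df))
    if (length(missing) > 0) {
      abort(paste0("missing channel column(s) in ", p, ": ",
                   paste(missing, collapse = ", ")),
            class = "gatescore_io_error")
    }
    out <- tibble(
      fsc_a = df[[channels[["fsc_a"]]]],
      ssc_a = df[[channels[["ssc_a"]]]],
      gfp = df[[channels[["gfp"]]]]
    )
    out$well_id <- if ("well_id" %in% names(df)) df$well_id else {
      sub("\\.[^.]*$", "", basename(p))
    }
    out
  })
}
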