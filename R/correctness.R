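# Replicate / strain / circuit correctness against the calibrated
# threshold, with the shaded summary-table semantics.

#' Classify replicates as correct or incorrect
#'
#' A retained replicate (well) is *correct* when its mean log10 GFP falls
#' on its strain's expected side of the threshold: at or above it for
#' expected-high strains, strictly below it for expected-low strains. A
#' well whose mean equals the threshold is classified high — a fixed
#' disclosed convention, since an exact tie carries no information either
#' way. Correctness is defined per replicate, not per cell: the readout of
#' a biological computation is the value prevailing over a population.
#'
#' By default the per-well statistic thresholded is the mean of log10 GFP;
#' `statistic = "log_of_mean"` instead thresholds log10 of the arithmetic
#' mean of linear GFP, for sensitivity analysis (requires a
#' `mean_gfp_linear` column).
#'
#' @param summaries retained well summaries with `mean_log_gfp` and
#'   `expected_output` columns.
#' @param threshold a `threshold_result` or a numeric threshold (log10 a.u.).
#' @param statistic which per-well statistic to threshold.
#' @return `summaries` with added columns `observed_output` (0/1) and
#'   `correct` (logical).
#' @export
classify_replicates <- function(summaries, threshold,
                                statistic = c("mean_of_log", "log_of_mean")) {
  statistic <- match.arg(statistic)
  t <- if (inherits(threshold, "threshold_result")) threshold$threshold else threshold
  stopifnot(is.numeric(t), length(t) == 1)
  if (!all(summaries$retained)) {
    abort("classify_replicates() expects only retained wells; filter first",
          class = "gatescore_correctness_error")
  }
  stat <- switch(statistic,
    mean_of_log = summaries$mean_log_gfp,
    log_of_mean = {
      if (!"mean_gfp_linear" %in% names(summaries)) {
        abort("statistic = 'log_of_mean' needs a mean_gfp_linear column",
              class = "gatescore_correctness_error")
      }
      log10(summaries$mean_gfp_linear)
    }
  )
  mutate(summaries,
    observed_output = as.integer(stat >= t),
    correct = .data$observed_output == .data$expected_output
  )
}

#' Score strains: proportion of correct replicates
#'
#' Aggregates classified replicates to one row per strain with the count
#' and proportion correct, shaded like the study's summary table: `green`
#' above 0.9, `gray` below 0.5, unshaded between. Strains with zero
#' retained replicates are reported with `n = 0` and `NA` proportion.
#'
#' @param classified output of [classify_replicates()].
#' @param green_min,gray_max shading cut points on the proportion correct.
#' @return Tibble: `strain`, `gate`, `input1`, `input2`, `n`, `n_correct`,
#'   `p_correct`, `shade`.
#' @export
score_strains <- function(classified, green_min = 0.9, gray_max = 0.5) {
  # WT has no gate; NOR00 is scored like any strain besides serving as
  # the positive control
  scored <- classified |>
    filter(.data$strain != "WT") |>
    group_by(.data$strain, .data$gate, .data$input1, .data$input2) |>
    summarise(
      n = n(),
      n_correct = sum(.data$correct),
      .groups = "drop"
    ) |>
    mutate(
      p_correct = if_else(.data$n > 0, .data$n_correct / .data$n, NA_real_),
      shade = dplyr::case_when(
        is.na(.data$p_correct) ~ NA_character_,
        .data$p_correct > green_min ~ "green",
        .data$p_correct < gray_max ~ "gray",
        TRUE ~ "none"
      )
    ) |>
    arrange(.data$gate, .data$input1, .data$input2)
  scored
}

#' Score circuits: the minimum over their four input strains
#'
#' A circuit computes its advertised function only if *every* input state
#' responds correctly — a gate wrong on one input is really a different
#' logic function — so circuit correctness is the minimum proportion
#' correct over its four strains. When one input fails systematically
#' (p_correct < 0.5) the "effective function" the circuit actually
#' computes (the truth table with that input's prevailing output) is named
#' in `effective_function` where it matches one of the six gates, e.g. a
#' NAND failing high on 11 behaves as constant high.
#'
#' @param strain_scores output of [score_strains()].
#' @return Tibble: `gate`, `p_correct`, `n_inputs_scored`, `complete`,
#'   `limiting_input`, `effective_function`.
#' @export
score_circuits <- function(strain_scores) {
  strain_scores |>
    group_by(.data$gate) |>
    dplyr::group_modify(function(d, key) {
      scored <- sum(!is.na(d$p_correct))
      tibble(
        n_inputs_scored = scored,
        complete = scored == 4L,
        p_correct = if (scored < 4L) NA_real_ else min(d$p_correct),
        limiting_input = if (scored == 0L) NA_character_ else {
          i <- which.min(d$p_correct)
          paste0(d$input1[i], d$input2[i])
        },
        effective_function = effective_function_name(
          key$gate, d$input1, d$input2, d$p_correct
        )
      )
    }) |>
    ungroup()
}

# Name the gate whose truth table matches the circuit's prevailing
# behaviour: inputs scoring < 0.5 are taken to output the complement of
# the design's expectation. NA when behaviour matches no standard gate or
# scores are incomplete.
effective_function_name <- function(gate, input1, input2, p_correct) {
  if (length(p_correct) != 4 || any(is.na(p_correct))) return(NA_character_)
  expected <- expected_output(gate, input1, input2)
  observed <- ifelse(p_correct < 0.5, 1L - expected, expected)
  tt <- gate_truth_tables()
  obs_tbl <- tibble(input1 = input1, input2 = input2, observed = observed)
  for (g in GATE_NAMES) {
    gt <- filter(tt, .data$gate == g)
    m <- left_join(obs_tbl, gt, by = c("input1", "input2"))
    if (all(m$observed == m$output)) return(g)
  }
  if (all(observed == 1L)) return("constant_high")
  if (all(observed == 0L)) return("constant_low")
  NA_character_
}

#' Campaign-level correctness summary
#'
#' Counts green / gray / unshaded strains, either pooled over all growth
#' conditions (the default — condition had no distinguishable effect in
#' the replication study, so replicates are pooled) or restricted to the
#' standard conditions (30 C, 16 h overnight, SC medium).
#'
#' @param classified output of [classify_replicates()] carrying condition
#'   columns (`temperature_C`, `overnight_hours`, `medium`).
#' @param grouping `"all_conditions"` or `"standard_conditions"`.
#' @param ... passed to [score_strains()].
#' @return List: `strain_scores`, `circuit_scores`, `counts` (one-row
#'   tibble with `n_strains`, `n_green`, `n_gray`, `n_unshaded`).
#' @export
summarize_campaign_correctness <- function(classified,
                                           grouping = c("all_conditions",
                                                        "standard_conditions"),
                                           ...) {
  grouping <- match.arg(grouping)
  if (grouping == "standard_conditions") {
    stopifnot(all(c("temperature_C", "overnight_hours", "medium") %in% names(classified)))
    classified <- filter(classified,
                         .data$temperature_C == 30,
                         .data$overnight_hours == 16,
                         .data$medium == "SC")
  }
  ss <- score_strains(classified, ...)
  list(
    strain_scores = ss,
    circuit_scores = score_circuits(ss),
    counts = tibble(
      grouping = grouping,
      n_strains = nrow(ss),
      n_green = sum(ss$shade == "green", na.rm = TRUE),
      n_gray = sum(ss$shade == "gray", na.rm = TRUE),
      n_unshaded = sum(ss$shade == "none", na.rm = TRUE)
    )
  )
}
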