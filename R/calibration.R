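# Control-based threshold calibration: one high/low GFP cut for all
# circuits, chosen to minimize the mean "wrong-direction" distance of the
# positive (NOR00) and negative (WT) control well means.

#' Mean wrong-direction distance of controls from a candidate threshold
#'
#' For threshold `t` (log10 a.u.) the cost is
#' \deqn{\big[\sum_{x \in neg,\; x > t}(x - t) + \sum_{x \in pos,\; x < t}(t - x)\big] / (n_{pos} + n_{neg})}
#' i.e. the distance *above* the threshold for negative-control well means
#' and *below* it for positive ones, averaged over all control wells.
#' Controls on the correct side contribute nothing. The function is
#' piecewise linear and convex in `t`.
#'
#' @param t candidate threshold(s), log10 a.u.; vectorized.
#' @param pos_means,neg_means mean log10 GFP of the positive / negative
#'   control wells.
#' @return Numeric cost, same length as `t`.
#' @examples
#' wrong_direction_cost(2.2, pos_means = c(2, 3), neg_means = c(1, 2.5))
#' # ((2.5-2.2) + (2.2-2.0)) / 4 = 0.125
#' @export
wrong_direction_cost <- function(t, pos_means, neg_means) {
  if (length(pos_means) == 0 || length(neg_means) == 0) {
    abort("both positive and negative control means are required",
          class = "gatescore_calibration_error")
  }
  stopifnot(all(is.finite(pos_means)), all(is.finite(neg_means)), all(is.finite(t)))
  n <- length(pos_means) + length(neg_means)
  vapply(t, function(tt) {
    (sum(pmax(neg_means - tt, 0)) + sum(pmax(tt - pos_means, 0))) / n
  }, numeric(1))
}

#' Optimal high/low threshold separating the control wells
#'
#' Finds the global minimizer of [wrong_direction_cost()] exactly. Because
#' the cost is piecewise linear and convex with breakpoints only at
#' control values, it suffices to evaluate it at the pooled sorted control
#' means: the minimizer is either a single breakpoint or a flat interval
#' between breakpoints (always the case when the controls separate
#' perfectly, where the cost is 0 on the whole gap). On a flat minimizing
#' interval the reported threshold is the interval midpoint — a symmetric,
#' reproducible tie-break — and the interval itself is reported.
#'
#' @inheritParams wrong_direction_cost
#' @return An object of class `threshold_result`: list with `threshold`
#'   (log10 a.u.), `threshold_au` (linear a.u.), `cost`, `interval`
#'   (length-2 numeric), `n_pos`, `n_neg`.
#' @examples
#' optimize_threshold(pos_means = c(3.0, 3.3), neg_means = c(1.0, 1.2))
#' # threshold 2.1, the midpoint of the zero-cost interval [1.2, 3.0]
#' @export
optimize_threshold <- function(pos_means, neg_means) {
  breaks <- sort(unique(c(pos_means, neg_means)))
  costs <- wrong_direction_cost(breaks, pos_means, neg_means)
  cmin <- min(costs)
  at_min <- which(costs <= cmin + 1e-12 * max(1, cmin))
  lo <- breaks[min(at_min)]
  hi <- breaks[max(at_min)]
  # the flat region may span the open gap between two adjacent breakpoints;
  # the midpoint of [lo, hi] is optimal by convexity either way
  threshold <- (lo + hi) / 2
  structure(
    list(
      threshold = threshold,
      threshold_au = 10^threshold,
      cost = wrong_direction_cost(threshold, pos_means, neg_means),
      interval = c(lo, hi),
      n_pos = length(pos_means),
      n_neg = length(neg_means)
    ),
    class = "threshold_result"
  )
}

#' Calibrate the GFP threshold from gated well summaries
#'
#' Data-frame front end to [optimize_threshold()]: pulls the retained
#' positive (NOR00) and negative (WT) control wells out of a well-summary
#' table and optimizes over their mean log10 GFP values. The result is a
#' *single* threshold for all circuits — composable gates need a common
#' high/low interpretation.
#'
#' @param summaries well-summary tibble (see [summarize_wells()]) with a
#'   `control_role` column.
#' @return A `threshold_result`.
#' @export
gfp_threshold <- function(summaries) {
  stopifnot(all(c("control_role", "mean_log_gfp", "retained") %in% names(summaries)))
  ctl <- filter(summaries, .data$retained, !is.na(.data$control_role))
  pos <- filter(ctl, .data$control_role == "positive")$mean_log_gfp
  neg <- filter(ctl, .data$control_role == "negative")$mean_log_gfp
  if (length(pos) == 0 || length(neg) == 0) {
    abort("need at least one retained positive and one negative control well",
          class = "gatescore_calibration_error")
  }
  optimize_threshold(pos_means = pos, neg_means = neg)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result> %.4f log10 a.u. (%.1f a.u.), cost %.4g\n  minimizing interval [%.4f, %.4f], %d positive / %d negative control wells\n",
    x$threshold, x$threshold_au, x$cost, x$interval[1], x$interval[2],
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Tidy a calibrated threshold
#'
#' @param x a `threshold_result`.
#' @param ... unused.
#' @return One-row tibble: `threshold`, `threshold_au`, `cost`,
#'   `interval_lo`, `interval_hi`, `n_pos`, `n_neg`.
#' @method tidy threshold_result
#' @export
tidy.threshold_result <- function(x, ...) {
  tibble(
    threshold = x$threshold, threshold_au = x$threshold_au, cost = x$cost,
    interval_lo = x$interval[1], interval_hi = x$interval[2],
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname tidy.threshold_result
#' @method glance threshold_result
#' @export
glance.threshold_result <- tidy.threshold_result

#' Write a threshold result as JSON
#'
#' @param x a `threshold_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_threshold_json <- function(x, path) {
  jsonlite::write_json(
    list(threshold = x$threshold, threshold_au = x$threshold_au,
         cost = x$cost, interval = x$interval,
         n_pos = x$n_pos, n_neg = x$n_neg),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
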