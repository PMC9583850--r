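# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit summation loops, prefix-sum grid
# search, character-level substring scans.

# element-wise summation of the wrong-direction distances (loops, no pmax)
naive_wrong_direction_cost <- function(t, pos, neg) {
  total <- 0
  for (x in neg) if (x > t) total <- total + (x - t)
  for (x in pos) if (x < t) total <- total + (t - x)
  total / (length(pos) + length(neg))
}

# dense grid search over candidate thresholds; cost at each grid point via
# sorted prefix sums (O(G log n), independent of the exact optimizer's
# breakpoint-balance logic)
grid_search_threshold <- function(pos, neg, step = 1e-4, pad = 0.5) {
  ts <- seq(min(c(pos, neg)) - pad, max(c(pos, neg)) + pad, by = step)
  sn <- sort(neg); cn <- cumsum(sn)
  sp <- sort(pos); cp <- cumsum(sp)
  i_n <- findInterval(ts, sn)                   # negatives <= t
  sum_above <- sum(sn) - ifelse(i_n == 0, 0, cn[pmax(i_n, 1)] * (i_n > 0))
  n_above <- length(sn) - i_n
  cost_neg <- sum_above - n_above * ts
  i_p <- findInterval(ts, sp)                   # positives <= t
  sum_below <- ifelse(i_p == 0, 0, cp[pmax(i_p, 1)] * (i_p > 0))
  cost_pos <- i_p * ts - sum_below
  cost <- (cost_neg + cost_pos) / (length(pos) + length(neg))
  list(threshold = ts[which.min(cost)], cost = min(cost))
}

# base-R reverse complement
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# double-loop exact substring scan over reads, forward and revcomp
naive_grna_scan <- function(reads, grna) {
  rcg <- rc_oracle(grna)
  w <- nchar(grna)
  for (r in reads) {
    L <- nchar(r)
    if (w > L) next
    for (i in seq_len(L - w + 1)) {
      ss <- substr(r, i, i + w - 1)
      if (ss == grna || ss == rcg) return(1L)
    }
  }
  0L
}

# bivariate normal cloud in log10 scatter coordinates, returned on the
# linear scale the package's functions expect
planted_scatter_cloud <- function(n, mean_fsc, mean_ssc, sd, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  tibble::tibble(
    fsc_a = 10^(mean_fsc + sd * z1),
    ssc_a = 10^(mean_ssc + sd * z2)
  )
}
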