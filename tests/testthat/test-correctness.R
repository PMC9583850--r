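mk_wells <- function(strain, means, condition = NULL) {
  spec <- parse_strain_label(strain)
  out <- tibble::tibble(
    well_id = paste0(strain, "_", seq_along(means)),
    strain = strain, gate = spec$gate, input1 = spec$input1,
    input2 = spec$input2, expected_output = spec$expected_output,
    is_control = spec$is_control, control_role = spec$control_role,
    mean_log_gfp = means, retained = TRUE
  )
  if (!is.null(condition)) out <- dplyr::bind_cols(out, condition)
  out
}

test_that("replicates classify by side of the threshold, ties going high", {
  ws <- mk_wells("NOR00", c(3.0, 2.0, 2.36))
  cl <- classify_replicates(ws, 2.36)
  expect_equal(cl$observed_output, c(1L, 0L, 1L))  # tie classifies high
  expect_equal(cl$correct, c(TRUE, FALSE, TRUE))
  # expected-low strain: a mean exactly at threshold is incorrect
  lo <- classify_replicates(mk_wells("AND00", 2.36), 2.36)
  expect_false(lo$correct)
  # unretained wells must be filtered before classification
  bad <- dplyr::mutate(ws, retained = FALSE)
  expect_error(classify_replicates(bad, 2.36),
               class = "gatescore_correctness_error")
})

test_that("strain scores count correct replicates and shade like the report", {
  means <- c(rep(3.0, 5), rep(1.0, 7))  # NAND11 expects low: 7 of 12 correct
  cl <- classify_replicates(mk_wells("NAND11", means), 2.36)
  ss <- score_strains(cl)
  expect_equal(ss$n, 12L)
  expect_equal(ss$n_correct, 7L)
  expect_equal(ss$p_correct, 7 / 12)
  expect_equal(ss$shade, "none")
  # shading boundaries
  hi <- score_strains(classify_replicates(mk_wells("OR11", rep(3, 20)), 2.36))
  expect_equal(hi$shade, "green")
  lo <- score_strains(classify_replicates(mk_wells("OR11", rep(1, 20)), 2.36))
  expect_equal(lo$p_correct, 0)
  expect_equal(lo$shade, "gray")
})

test_that("circuit score is the minimum over the four input strains", {
  wells <- dplyr::bind_rows(
    mk_wells("NAND00", rep(3, 10)), mk_wells("NAND01", rep(3, 10)),
    mk_wells("NAND10", rep(3, 10)),
    mk_wells("NAND11", c(rep(3, 7), rep(1, 5)))  # 5/12 correct (expects low)
  )
  ss <- score_strains(classify_replicates(wells, 2.36))
  cs <- score_circuits(ss)
  expect_equal(cs$p_correct, 5 / 12)
  expect_equal(cs$limiting_input, "11")
  # a NAND stuck high on 11 behaves as constant high
  stuck <- dplyr::bind_rows(
    mk_wells("NAND00", rep(3, 10)), mk_wells("NAND01", rep(3, 10)),
    mk_wells("NAND10", rep(3, 10)), mk_wells("NAND11", rep(3, 10))
  )
  cs2 <- score_circuits(score_strains(classify_replicates(stuck, 2.36)))
  expect_equal(cs2$p_correct, 0)
  expect_equal(cs2$effective_function, "constant_high")
  # incomplete circuits are reported as such
  partial <- score_strains(classify_replicates(
    dplyr::bind_rows(mk_wells("XOR00", rep(1, 5)), mk_wells("XOR01", rep(3, 5))),
    2.36))
  cp <- score_circuits(partial)
  expect_false(cp$complete)
  expect_true(is.na(cp$p_correct))
})

test_that("p_correct is invariant to ordering and batch splits", {
  set.seed(83)
  means <- rnorm(24, 2.4, 0.6)
  wells <- mk_wells("XNOR11", means)
  base <- score_strains(classify_replicates(wells, 2.36))
  perm <- wells[sample.int(nrow(wells)), ]
  expect_equal(score_strains(classify_replicates(perm, 2.36))$p_correct,
               base$p_correct)
  halves <- dplyr::bind_rows(wells[1:12, ], wells[13:24, ])
  expect_equal(score_strains(classify_replicates(halves, 2.36))$p_correct,
               base$p_correct)
})

test_that("raising the threshold moves scores monotonically by expected side", {
  set.seed(89)
  hi_wells <- mk_wells("OR11", rnorm(50, 2.4, 0.8))   # expects high
  lo_wells <- mk_wells("AND01", rnorm(50, 2.4, 0.8))  # expects low
  p_hi <- function(t) score_strains(classify_replicates(hi_wells, t))$p_correct
  p_lo <- function(t) score_strains(classify_replicates(lo_wells, t))$p_correct
  ts <- seq(1, 4, by = 0.25)
  expect_true(all(diff(vapply(ts, p_hi, numeric(1))) <= 1e-12))
  expect_true(all(diff(vapply(ts, p_lo, numeric(1))) >= -1e-12))
})

test_that("campaign summaries count shades per condition grouping", {
  std <- growth_condition()
  warm <- growth_condition(temperature_C = 37)
  wells <- dplyr::bind_rows(
    mk_wells("AND11", rep(3, 10), std),    # green under standard
    mk_wells("AND00", rep(1, 10), std),    # green under standard
    mk_wells("OR01", rep(1, 10), warm)     # gray, but non-standard condition
  )
  all_g <- summarize_campaign_correctness(classify_replicates(wells, 2.36),
                                          "all_conditions")
  expect_equal(all_g$counts$n_strains, 3L)
  expect_equal(all_g$counts$n_green, 2L)
  expect_equal(all_g$counts$n_gray, 1L)
  std_g <- summarize_campaign_correctness(classify_replicates(wells, 2.36),
                                          "standard_conditions")
  expect_equal(std_g$counts$n_strains, 2L)
  expect_equal(std_g$counts$n_gray, 0L)
})

test_that("the alternative log-of-mean statistic is available behind the switch", {
  ws <- dplyr::mutate(mk_wells("NOR00", c(2.0)), mean_gfp_linear = 500)
  # mean of log says low; log of arithmetic mean (2.7) says high
  expect_false(classify_replicates(ws, 2.36)$correct)
  expect_true(classify_replicates(ws, 2.36, statistic = "log_of_mean")$correct)
  expect_error(classify_replicates(dplyr::select(ws, -mean_gfp_linear), 2.36,
                                   statistic = "log_of_mean"),
               class = "gatescore_correctness_error")
})
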