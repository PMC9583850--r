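small_cfg <- function(...) {
  sim_config(seed = 11L, n_replicates = 2L, events_per_well = 500L, ...)
}

test_that("well event tables have the configured size and respect the ceiling", {
  cfg <- sim_config(seed = 3L, events_per_well = 30000L)
  ev <- simulate_well_events("AND11", "high", cfg, seed = 42L)
  expect_equal(nrow(ev), 30000L)
  for (ch in c("fsc_a", "ssc_a", "gfp")) {
    expect_true(all(ev[[ch]] >= 0))
    expect_true(all(ev[[ch]] <= cfg$saturation_limit))
  }
})

test_that("a degenerate mixture puts every event in one cluster", {
  cfg <- sim_config(
    seed = 5L, events_per_well = 2000L,
    scatter_clusters = tibble::tibble(mean_fsc = 5, mean_ssc = 5, sd = 0.05,
                                      cor = 0.9, weight = 1),
    debris = list(mean_fsc = 3, mean_ssc = 3, sd = 0.3, fraction = 0)
  )
  ev <- simulate_well_events("WT", "low", cfg, seed = 1L)
  # all events within a tight band around the single cluster center
  expect_true(all(abs(log10(ev$fsc_a) - 5) < 0.05 * 6))
  expect_true(all(abs(log10(ev$ssc_a) - 5) < 0.05 * 6))
})

test_that("saturation clipping matches a Monte-Carlo clip-fraction oracle", {
  # cluster mean above the ceiling: a large fraction of events must clip
  lim <- 1048575
  mu <- 6.1; sdev <- 0.15
  cfg <- sim_config(
    seed = 9L, events_per_well = 30000L,
    scatter_clusters = tibble::tibble(mean_fsc = mu, mean_ssc = 5, sd = sdev,
                                      cor = 0.9, weight = 1),
    debris = list(mean_fsc = 3, mean_ssc = 3, sd = 0.3, fraction = 0)
  )
  ev <- simulate_well_events("WT", "low", cfg, seed = 2L)
  observed <- mean(ev$fsc_a == lim)
  set.seed(99)
  oracle <- mean(rnorm(1e6, mu, sdev) > log10(lim)) # empirical clip fraction
  se <- sqrt(oracle * (1 - oracle) / nrow(ev))
  expect_lt(abs(observed - oracle), 3 * se)
})

test_that("the same seed reproduces the campaign byte for byte", {
  cfg <- small_cfg()
  a <- simulate_campaign(cfg)
  b <- simulate_campaign(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$layout, b$layout)
  expect_identical(a$plate_reader, b$plate_reader)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth, b$truth)
})

test_that("per-well substreams are independent: growing the campaign leaves existing wells unchanged", {
  a <- simulate_campaign(sim_config(seed = 21L, n_replicates = 2L,
                                    events_per_well = 300L))
  b <- simulate_campaign(sim_config(seed = 21L, n_replicates = 3L,
                                    events_per_well = 300L))
  key <- function(camp) {
    lay <- camp$layout
    ev <- dplyr::left_join(camp$events,
                           dplyr::select(lay, well_id, strain, replicate),
                           by = "well_id")
    dplyr::arrange(dplyr::select(ev, -well_id), strain, replicate, fsc_a)
  }
  common_a <- key(a)
  common_b <- dplyr::filter(key(b), replicate <= 2L)
  expect_equal(common_a, common_b)
})

test_that("with no failures every well's true mode equals its expected output", {
  camp <- simulate_campaign(small_cfg(well_failure_rate = 0))
  tw <- camp$truth$wells
  expect_false(any(tw$failed))
  expect_identical(tw$true_mode,
                   ifelse(tw$expected_output == 1L, "high", "low"))
  # wells are tightly clustered: per-replicate SD of log10 GFP stays well
  # under the 0.613 log-unit bound the defaults are designed around
  sds <- camp$events |>
    dplyr::group_by(well_id) |>
    dplyr::summarise(s = sd(log10(pmax(gfp, 1))), .groups = "drop")
  expect_true(all(sds$s <= 0.613))
})

test_that("planted well-failure rates are recovered within binomial error", {
  # 200 NOR11 wells at failure rate 0.5
  panel <- strain_panel()
  sub <- dplyr::filter(panel, strain %in% c("NOR11", "WT", "NOR00"))
  cfg <- sim_config(seed = 31L, n_replicates = 200L, events_per_well = 20L,
                    strains = sub, well_failure_rate = c(NOR11 = 0.5),
                    reads = list(n_per_strain = 5L, length = 60L,
                                 genome_size = 1e5))
  camp <- simulate_campaign(cfg)
  tw <- dplyr::filter(camp$truth$wells, strain == "NOR11")
  expect_equal(nrow(tw), 200L)
  frac_wrong <- mean(tw$failed)
  expect_lt(abs(frac_wrong - 0.5), 3 * sqrt(0.5 * 0.5 / 200))
  # controls never fail under a scalar/omitted rate
  expect_false(any(camp$truth$wells$failed[camp$truth$wells$strain != "NOR11"]))
})

test_that("median final OD increases with target OD with diminishing returns", {
  conds <- dplyr::bind_rows(lapply(c(0.0003, 0.003, 0.03, 0.3),
                                   function(d) growth_condition(target_od = d)))
  cfg <- sim_config(seed = 41L, n_replicates = 16L, events_per_well = 20L,
                    wells_per_plate = 93L, conditions = conds,
                    reads = list(n_per_strain = 2L, length = 40L,
                                 genome_size = 1e5))
  camp <- simulate_campaign(cfg)
  med <- camp$plate_reader |>
    dplyr::group_by(target_od) |>
    dplyr::summarise(m = stats::median(final_od), .groups = "drop") |>
    dplyr::arrange(target_od)
  expect_equal(nrow(med), 4L)
  expect_true(all(diff(med$m) > 0))
  # diminishing rate of return per unit target OD
  gain_per_od <- diff(med$m) / diff(med$target_od)
  expect_true(all(diff(gain_per_od) < 0))
})

test_that("campaigns write to plain-text files that read back", {
  dir <- withr::local_tempdir()
  camp <- simulate_campaign(sim_config(
    seed = 51L, n_replicates = 1L, events_per_well = 50L,
    strains = dplyr::filter(strain_panel(), strain %in% c("AND00", "WT", "NOR00")),
    reads = list(n_per_strain = 4L, length = 50L, genome_size = 1e5)
  ))
  write_campaign(camp, dir)
  ev_files <- list.files(file.path(dir, "events"), full.names = TRUE)
  expect_equal(length(ev_files), nrow(camp$layout))
  back <- read_event_csv(ev_files[1])
  expect_equal(nrow(back), 50L)
  reads <- read_strain_reads(list.files(file.path(dir, "reads"), full.names = TRUE))
  expect_setequal(names(reads), names(camp$reads))
  expect_equal(sort(unname(unlist(reads["AND00"]))), sort(camp$reads$AND00))
})
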