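test_that("exact gRNA search finds forward and reverse-complement hits only", {
  expect_equal(search_grna("TTACGTACGTTT", "ACGTACGT"), 1L)
  # read equal to the reverse complement of a flanked gRNA
  g <- "ACGTACGT"
  flanked <- paste0("TT", g, "CC")
  expect_equal(search_grna(rc_oracle(flanked), g), 1L)
  expect_equal(search_grna("AAAAAAAAAA", g), 0L)
  # ambiguous bases in reads never match
  expect_equal(search_grna("TTACGTNCGTTT", "ACGTACGT"), 0L)
  expect_error(search_grna("ACGT", "ACNT"), class = "gatescore_dnaseq_error")
  # configurable minimum read support
  reads <- c(paste0("AA", g, "AA"), "CCCCCCCCCCCC")
  expect_equal(search_grna(reads, g, min_reads = 1), 1L)
  expect_equal(search_grna(reads, g, min_reads = 2), 0L)
})

test_that("search agrees with a naive double-loop scan on random planted reads", {
  set.seed(109)
  lib <- synthetic_grna_library(n = 6, width = 12, seed = 7)
  mk_read <- function() paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                              collapse = "")
  reads <- replicate(200, mk_read())
  # plant some gRNAs, forward or revcomp, at random positions
  for (i in 1:30) {
    g <- sample(lib$sequence, 1)
    ins <- if (runif(1) < 0.5) g else rc_oracle(g)
    slot <- sample(200, 1); pos <- sample(40 - 12 + 1, 1)
    r <- reads[slot]
    substr(r, pos, pos + 11) <- ins
    reads[slot] <- r
  }
  for (g in lib$sequence) {
    expect_equal(search_grna(reads, g), naive_grna_scan(reads, g), info = g)
  }
  # invariance under reverse-complementing every read
  rc_reads <- vapply(reads, rc_oracle, character(1), USE.NAMES = FALSE)
  for (g in lib$sequence) {
    expect_equal(search_grna(rc_reads, g), search_grna(reads, g))
  }
})

test_that("design matrix equals an independent set-membership recomputation", {
  lib <- synthetic_grna_library(seed = 3)
  panel <- strain_panel()
  dm <- build_design_matrix(panel, lib)
  # independent recomputation by raw set membership
  for (i in sample(nrow(dm), 50)) {
    s <- dm$strain[i]; g <- dm$grna[i]
    parts <- panel$grnas[[which(panel$strain == s)]]
    expect_identical(dm$present[i], as.integer(g %in% parts))
  }
  # empty part list -> all-zero row; identical designs -> identical rows
  wt_row <- dplyr::filter(dm, strain == "WT")
  expect_true(all(wt_row$present == 0L))
  expect_error(
    build_design_matrix(
      tibble::tibble(strain = "X", grnas = list("not_a_part")), lib),
    class = "gatescore_dnaseq_error")
})

test_that("results matrix reproduces generator ground truth, flagging missing strains", {
  anomalies <- tibble::tibble(
    strain = c("XOR01", "NAND00"),
    grna = c("r1", "r3"),
    type = c("drop", "add")
  )
  cfg <- sim_config(seed = 113L, n_replicates = 1L, events_per_well = 20L,
                    dnaseq_anomalies = anomalies,
                    reads = list(n_per_strain = 40L, length = 80L,
                                 genome_size = 1e5))
  camp <- simulate_campaign(cfg)
  rm_ <- build_results_matrix(camp$reads, camp$grna_library)
  joined <- dplyr::inner_join(rm_, camp$truth$results,
                              by = c("strain", "grna"),
                              suffix = c("_obs", "_truth"))
  expect_equal(nrow(joined), nrow(camp$truth$results))
  expect_identical(joined$present_obs, joined$present_truth)
  # a strain without reads is flagged NA, not zero-filled
  expect_warning(
    rm_na <- build_results_matrix(camp$reads["WT"], camp$grna_library,
                                  strains = c("WT", "GHOST")),
    "no read set")
  expect_true(all(is.na(dplyr::filter(rm_na, strain == "GHOST")$present)))
})

test_that("anomaly classification matches an element-wise comparison oracle", {
  set.seed(127)
  strains <- paste0("s", 1:24)
  grnas <- paste0("r", 1:13)
  grid <- tidyr::expand_grid(strain = strains, grna = grnas)
  design <- dplyr::mutate(grid, present = rbinom(dplyr::n(), 1, 0.5))
  results <- dplyr::mutate(grid, present = rbinom(dplyr::n(), 1, 0.5))
  an <- find_anomalies(design, results)
  # element-wise oracle
  d <- design$present; r <- results$present
  expect_equal(sum(an$cells$status == "unexpected_absence"),
               sum(d == 1 & r == 0))
  expect_equal(sum(an$cells$status == "unexpected_presence"),
               sum(d == 0 & r == 1))
  expect_equal(an$n_anomalies, sum(d != r))
  # identity comparison is anomaly-free; swapping roles swaps the classes
  expect_equal(find_anomalies(design, design)$n_anomalies, 0L)
  sw <- find_anomalies(results, design)
  expect_equal(sum(sw$cells$status == "unexpected_absence"),
               sum(an$cells$status == "unexpected_presence"))
  expect_error(find_anomalies(design, results[1:10, ]),
               class = "gatescore_dnaseq_error")
})

test_that("design compatibility reasons over required and observed parts", {
  lib_names <- c("r1", "r6", "r9", "r10")
  candidates <- tibble::tibble(
    strain = c("designA", "designB", "designC"),
    grnas = list(c("r1", "r10"), c("r1", "r9"), c("r6", "r10"))
  )
  # r1 and r9 absent from the observation: designs requiring them drop out
  observed <- c(r1 = 0L, r6 = 1L, r9 = 0L, r10 = 1L)
  expect_equal(design_compatibility(observed, candidates), "designC")
  # all candidates require the missing r1 -> empty set
  all_r1 <- dplyr::filter(candidates, strain != "designC")
  expect_equal(design_compatibility(observed, all_r1), character(0))
  # exact-set candidate passes even under strict matching
  exact <- tibble::tibble(strain = "designD", grnas = list(c("r6", "r10")))
  expect_equal(design_compatibility(observed, exact, strict = TRUE), "designD")
  # strict mode disqualifies designs not expecting an observed part
  expect_equal(design_compatibility(c(r1 = 1L, r6 = 1L, r9 = 0L, r10 = 1L),
                                    exact, strict = TRUE), character(0))
  expect_equal(design_compatibility(observed, candidates[0, ]), character(0))
})

test_that("coverage estimates follow base-count arithmetic", {
  reads <- list(
    s1 = replicate(1000, paste(rep("A", 100), collapse = "")),
    s2 = character(0)
  )
  cov <- coverage_estimate(reads, genome_size = 100000)
  expect_equal(cov$coverage[cov$strain == "s1"], 1.0)
  expect_equal(cov$coverage[cov$strain == "s2"], 0)
  expect_equal(cov$total_bases[cov$strain == "s1"], 100000)
})

test_that("gRNA libraries read from FASTA and TSV", {
  lib <- synthetic_grna_library(n = 4, seed = 5)
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(paste0(">", lib$grna, "\n", lib$sequence), fa)
  expect_equal(read_grna_library(fa), lib)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(lib, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(read_grna_library(tsv), lib, ignore_attr = TRUE)
})
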