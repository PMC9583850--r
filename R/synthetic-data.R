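# Synthetic campaign generator: flow-cytometry events, plate layouts,
# plate-reader readings and sequencing reads with the statistical structure
# the downstream analysis assumes, plus the ground truth needed to test it.

#' Simulation configuration for a synthetic logic-gate campaign
#'
#' Defaults define a campaign emulating the replication study's measurement
#' structure: 30,000 flow-cytometry events per well; 96-well plates holding
#' 93 experimental wells, one WT and one NOR00 control well (three wells
#' are reserved for calibration beads and not simulated); scatter events
#' drawn from a two-cluster log10-normal mixture plus a debris cluster,
#' hard-clipped at the instrument ceiling of 1,048,575 a.u.; per-cell log10
#' GFP tightly clustered around a well-level high or low mode about two
#' log-units apart; a Monod-style diminishing-return map from target OD to
#' final OD; and fixed-length reads embedding each designed gRNA once.
#'
#' Whole-well failures: with probability `well_failure_rate` (scalar, or a
#' named per-strain vector) a well expresses the *opposite* mode from its
#' strain's expected output — every cell in the well shifts together, so
#' failures surface as replicate-level bimodality, not within-well spread.
#'
#' @param seed integer seed; all randomness fans out from it through
#'   deterministic per-well substreams.
#' @param n_replicates experimental replicates (wells) per strain.
#' @param events_per_well flow-cytometry events recorded per well.
#' @param wells_per_plate experimental wells per 96-well plate.
#' @param scatter_clusters tibble with one row per scatter cluster:
#'   `mean_fsc`, `mean_ssc` (log10 a.u.), `sd` (log10), `cor` (within-cluster
#'   correlation of log10 SSC_A with log10 FSC_A) and `weight`.
#' @param debris list with `mean_fsc`, `mean_ssc`, `sd` (log10) and
#'   `fraction`, the proportion of events that are debris.
#' @param saturation_limit instrument ceiling in a.u.; all channels are
#'   clipped to `[0, saturation_limit]`.
#' @param gfp_low,gfp_high lists with `mean` and `sd` of per-cell log10 GFP
#'   for the low and high output modes.
#' @param well_effect_sd SD (log10) of the per-well random shift shared by
#'   all cells in a well.
#' @param well_failure_rate probability a well expresses the wrong mode;
#'   scalar or named per-strain vector (strains not named get 0). Controls
#'   fail only if named explicitly.
#' @param growth list of growth-model parameters: `od_max` and `K` of the
#'   saturating map `final = od_max * D / (D + K)` from target OD `D`,
#'   `sdlog` multiplicative log-normal noise, and `initial_meanlog`,
#'   `initial_sdlog` for the post-recovery (pre-dilution) OD.
#' @param platereader list with `gain` (a.u. fluorescence per OD per unit
#'   per-cell GFP) and `cv`, the multiplicative noise coefficient of
#'   variation of the bulk GFP reading.
#' @param reads list with `n_per_strain`, `length` (nt) and
#'   `genome_size` (bases, used only for coverage estimates).
#' @param conditions tibble of growth conditions (see [growth_condition()]);
#'   rows are recycled across plates.
#' @param strains strain panel tibble; defaults to [strain_panel()].
#' @param dnaseq_anomalies tibble with columns `strain`, `grna`, `type`
#'   (`"drop"` to remove a designed gRNA from the reads, `"add"` to embed
#'   an undesigned one); default none.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_replicates = 12L,
                       events_per_well = 30000L,
                       wells_per_plate = 93L,
                       scatter_clusters = tibble(
                         mean_fsc = c(5.00, 5.50),
                         mean_ssc = c(5.45, 5.25),
                         sd       = c(0.15, 0.15),
                         cor      = c(0.95, 0.95),
                         weight   = c(0.4, 0.6)
                       ),
                       debris = list(mean_fsc = 3.2, mean_ssc = 3.0,
                                     sd = 0.35, fraction = 0.05),
                       saturation_limit = 1048575,
                       gfp_low  = list(mean = 1.5, sd = 0.25),
                       gfp_high = list(mean = 3.5, sd = 0.25),
                       well_effect_sd = 0.08,
                       well_failure_rate = 0,
                       growth = list(od_max = 2.0, K = 0.01, sdlog = 0.15,
                                     initial_meanlog = 0, initial_sdlog = 0.2,
                                     vigor_sdlog = 0.15),
                       platereader = list(gain = 1.0, cv = 0.05),
                       reads = list(n_per_strain = 60L, length = 100L,
                                    genome_size = 1.2e7),
                       conditions = growth_condition(),
                       strains = strain_panel(),
                       dnaseq_anomalies = NULL) {
  stopifnot(
    events_per_well > 0, n_replicates > 0,
    wells_per_plate >= 1, wells_per_plate <= 93,  # 96 minus 3 bead wells
    all(scatter_clusters$sd > 0), all(scatter_clusters$weight >= 0),
    debris$fraction >= 0, debris$fraction <= 1,
    saturation_limit > 0,
    gfp_low$sd > 0, gfp_high$sd > 0
  )
  if (abs(sum(scatter_clusters$weight) - 1) > 1e-8) {
    scatter_clusters$weight <- scatter_clusters$weight / sum(scatter_clusters$weight)
  }
  structure(
    list(
      seed = as.integer(seed), n_replicates = as.integer(n_replicates),
      events_per_well = as.integer(events_per_well),
      wells_per_plate = as.integer(wells_per_plate),
      scatter_clusters = scatter_clusters, debris = debris,
      saturation_limit = saturation_limit,
      gfp_low = gfp_low, gfp_high = gfp_high,
      well_effect_sd = well_effect_sd,
      well_failure_rate = well_failure_rate,
      growth = growth, platereader = platereader, reads = reads,
      conditions = conditions, strains = strains,
      dnaseq_anomalies = dnaseq_anomalies
    ),
    class = "sim_config"
  )
}

# Deterministic 31-bit substream seed from a master seed and a string key,
# so each well/stage gets an independent stream and adding a well never
# perturbs the draws of another.
substream_seed <- function(seed, key) {
  h <- as.double(seed %% 2147483647L)
  for (v in utf8ToInt(key)) {
    h <- (h * 31 + v) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Bivariate normal in (log10 FSC, log10 SSC) with common SD and correlation.
rbinorm_log10 <- function(n, mean_fsc, mean_ssc, sd, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(fsc = mean_fsc + sd * z1, ssc = mean_ssc + sd * z2)
}

#' Simulate the flow-cytometry events of one well
#'
#' Draws `events_per_well` events from the debris + two-cluster scatter
#' mixture and a log10-normal GFP distribution centred on the well's output
#' mode (all cells in a well share the mode and a small per-well shift).
#' All channels are clipped to `[0, saturation_limit]` on the linear scale,
#' emulating the instrument ceiling.
#'
#' @param strain strain label (carried into the output).
#' @param mode `"high"` or `"low"`: the well's true output mode.
#' @param cfg a [sim_config()].
#' @param seed integer seed for this well's substream.
#' @return A tibble with columns `fsc_a`, `ssc_a`, `gfp` (linear a.u.).
#' @export
simulate_well_events <- function(strain, mode = c("high", "low"), cfg = sim_config(),
                                 seed = cfg$seed) {
  mode <- match.arg(mode)
  n <- cfg$events_per_well
  with_seed(seed, {
    n_debris <- stats::rbinom(1L, n, cfg$debris$fraction)
    n_cells <- n - n_debris
    cl <- cfg$scatter_clusters
    assign_k <- if (nrow(cl) == 1L) rep(1L, n_cells) else {
      sample.int(nrow(cl), n_cells, replace = TRUE, prob = cl$weight)
    }
    log_sc <- matrix(NA_real_, nrow = n_cells, ncol = 2)
    for (k in seq_len(nrow(cl))) {
      idx <- which(assign_k == k)
      if (length(idx) > 0) {
        log_sc[idx, ] <- rbinorm_log10(length(idx), cl$mean_fsc[k], cl$mean_ssc[k],
                                       cl$sd[k], cl$cor[k])
      }
    }
    if (n_debris > 0) {
      deb <- rbinorm_log10(n_debris, cfg$debris$mean_fsc, cfg$debris$mean_ssc,
                           cfg$debris$sd, 0)
      log_sc <- rbind(log_sc, deb)
    }
    gfp_par <- if (mode == "high") cfg$gfp_high else cfg$gfp_low
    well_shift <- stats::rnorm(1L, 0, cfg$well_effect_sd)
    log_gfp <- stats::rnorm(n, gfp_par$mean + well_shift, gfp_par$sd)
    clip <- function(x) pmin(pmax(10^x, 0), cfg$saturation_limit)
    tibble(
      fsc_a = clip(log_sc[, 1]),
      ssc_a = clip(log_sc[, 2]),
      gfp = clip(log_gfp)
    )
  })
}

failure_rate_for <- function(cfg, strain, is_control) {
  wfr <- cfg$well_failure_rate
  if (is.null(names(wfr))) {
    if (is_control) 0 else wfr[1]
  } else {
    unname(wfr[strain] %|na|% 0)
  }
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

#' Simulate a full synthetic campaign
#'
#' Generates plate layouts (randomized well positions), per-well event
#' tables, plate-reader initial/final OD and bulk GFP readings, per-strain
#' sequencing reads, and the ground truth (true well modes, injected DNAseq
#' anomalies) that tests score against.
#'
#' Reproducibility contract: the same configuration and seed give an
#' identical dataset, and each well draws from its own substream keyed by
#' strain and replicate, so enlarging the campaign does not change the
#' events of existing wells.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `gate_campaign`: a list with elements
#'   `layout` (one row per simulated well), `events` (all wells' events,
#'   keyed by `well_id`), `plate_reader`, `reads` (named list of character
#'   vectors per strain), `grna_library`, `truth` (list: `wells` with true
#'   modes, `results` presence tibble), `config` and `seed`.
#' @export
simulate_campaign <- function(cfg = sim_config()) {
  strains <- cfg$strains

  # every panel strain gets n_replicates wells; NOR00 wells double as the
  # positive controls and WT wells as the negative controls
  wells <- tidyr::expand_grid(
    strain = strains$strain,
    replicate = seq_len(cfg$n_replicates)
  )
  n_plates <- ceiling(nrow(wells) / cfg$wells_per_plate)
  wells <- with_seed(substream_seed(cfg$seed, "layout/shuffle"), {
    wells[sample.int(nrow(wells)), , drop = FALSE]
  })
  wells$plate <- rep(seq_len(n_plates), each = cfg$wells_per_plate)[seq_len(nrow(wells))]
  layout <- arrange(wells, .data$plate)

  # randomized positions within each plate; 3 wells/plate reserved for beads
  all_pos <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  bead_pos <- c("H10", "H11", "H12")
  layout <- layout |>
    group_by(.data$plate) |>
    mutate(position = with_seed(
      substream_seed(cfg$seed, paste0("layout/pos/", .data$plate[1])),
      sample(setdiff(all_pos, bead_pos), n())
    )) |>
    ungroup()

  cond <- cfg$conditions[((seq_len(n_plates) - 1L) %% nrow(cfg$conditions)) + 1L, ]
  cond$plate <- seq_len(n_plates)
  layout <- left_join(layout, cond, by = "plate")
  layout <- left_join(layout,
                      select(strains, "strain", "gate", "input1", "input2",
                             "expected_output", "is_control", "control_role"),
                      by = "strain")
  layout <- mutate(layout,
    control_role = if_else(.data$strain == "WT", "negative", .data$control_role),
    well_id = paste0("P", .data$plate, "_", .data$position)
  )

  # true output mode per well: expected output, flipped on whole-well failure
  layout$failed <- purrr::pmap_lgl(
    list(layout$strain, layout$replicate,
         layout$is_control | layout$strain == "WT"),
    function(s, r, ctl) {
      rate <- failure_rate_for(cfg, s, ctl)
      if (rate <= 0) return(FALSE)
      with_seed(substream_seed(cfg$seed, paste0("fail/", s, "/", r)),
                stats::runif(1) < rate)
    }
  )
  layout$true_mode <- if_else(xor(layout$expected_output == 1L, layout$failed),
                              "high", "low")

  events <- purrr::pmap(
    list(layout$strain, layout$replicate, layout$true_mode, layout$well_id),
    function(s, r, m, w) {
      ev <- simulate_well_events(s, m, cfg,
                                 seed = substream_seed(cfg$seed, paste0("events/", s, "/", r)))
      ev$well_id <- w
      ev
    }
  ) |> bind_rows()

  # plate reader: pre-dilution OD, saturating growth in target OD, bulk GFP
  mean_linear_gfp <- events |>
    group_by(.data$well_id) |>
    summarise(mean_gfp_linear = mean(.data$gfp), .groups = "drop")
  gr <- cfg$growth
  vigor_sdlog <- gr$vigor_sdlog %||% 0
  plate_reader <- layout |>
    left_join(mean_linear_gfp, by = "well_id") |>
    mutate(
      # per-well growth vigor shared by the recovery and growth phases, so
      # wells that recovered densely also tend to grow densely
      .vigor = purrr::pmap_dbl(list(.data$strain, .data$replicate), function(s, r) {
        with_seed(substream_seed(cfg$seed, paste0("vigor/", s, "/", r)),
                  stats::rnorm(1, 0, vigor_sdlog))
      }),
      initial_od = purrr::pmap_dbl(
        list(.data$strain, .data$replicate, .data$.vigor),
        function(s, r, v) {
          with_seed(substream_seed(cfg$seed, paste0("od0/", s, "/", r)),
                    stats::rlnorm(1, gr$initial_meanlog + v, gr$initial_sdlog))
        }),
      final_od = purrr::pmap_dbl(
        list(.data$strain, .data$replicate, .data$target_od, .data$.vigor),
        function(s, r, d, v) {
          with_seed(substream_seed(cfg$seed, paste0("od1/", s, "/", r)),
                    gr$od_max * d / (d + gr$K) *
                      stats::rlnorm(1, v, gr$sdlog))
        }),
      bulk_gfp = purrr::pmap_dbl(
        list(.data$strain, .data$replicate, .data$final_od, .data$mean_gfp_linear),
        function(s, r, od, g) {
          with_seed(substream_seed(cfg$seed, paste0("prgfp/", s, "/", r)),
                    od * g * cfg$platereader$gain *
                      stats::rlnorm(1, 0, cfg$platereader$cv))
        })
    ) |>
    select("well_id", "plate", "strain", "replicate", "initial_od",
           "final_od", "bulk_gfp", "temperature_C", "overnight_hours",
           "medium", "target_od")  # .vigor is internal and dropped here

  lib <- synthetic_grna_library(seed = substream_seed(cfg$seed, "library"))
  dna <- simulate_reads(strains, lib, cfg)

  structure(
    list(
      layout = layout,
      events = events,
      plate_reader = plate_reader,
      reads = dna$reads,
      grna_library = lib,
      truth = list(
        wells = select(layout, "well_id", "strain", "replicate",
                       "expected_output", "true_mode", "failed"),
        results = dna$truth_presence
      ),
      config = cfg,
      seed = cfg$seed
    ),
    class = "gate_campaign"
  )
}

#' @export
print.gate_campaign <- function(x, ...) {
  cat("<gate_campaign>\n")
  cat("  wells:  ", nrow(x$layout), " (", sum(x$layout$strain != "WT"),
      " experimental-strain) on ", max(x$layout$plate), " plates\n", sep = "")
  cat("  events: ", nrow(x$events), " (", x$config$events_per_well, "/well)\n", sep = "")
  cat("  strains with reads: ", length(x$reads), "\n", sep = "")
  cat("  seed:   ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Synthetic gRNA library
#'
#' Random 20-nt sequences named `r1`, `r2`, ... standing in for a real gRNA
#' part library (the circuits' true sequences are inputs the user supplies;
#' this library is synthetic and exists so the sequence-verification stage
#' is exercisable end to end).
#'
#' @param n number of gRNAs.
#' @param width sequence length in nt.
#' @param seed integer seed.
#' @return A tibble with columns `grna`, `sequence`.
#' @export
synthetic_grna_library <- function(n = 13L, width = 20L, seed = 1L) {
  with_seed(seed, {
    tibble(
      grna = paste0("r", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
      }, character(1))
    )
  })
}

#' Synthetic per-strain gRNA part lists
#'
#' A fixed, synthetic assignment of gRNA parts (coding sequences and target
#' sites, which share names) to the 24 experimental strains and the NOR00
#' control: each gate family uses a small internal part set, `r11`/`r12`
#' mark expressed input signals, and `r10` is the common output reporter.
#' This layout is a stand-in for the unpublished real designs.
#'
#' @return A tibble with columns `strain`, `grna`.
#' @export
synthetic_grna_parts <- function() {
  internals <- list(
    AND = c("r1", "r2"), OR = c("r3", "r4"), NAND = c("r1", "r5"),
    NOR = c("r6"), XOR = c("r1", "r6", "r7", "r9"), XNOR = c("r2", "r8", "r9")
  )
  rows <- purrr::map_dfr(names(internals), function(g) {
    purrr::map_dfr(c("00", "01", "10", "11"), function(bits) {
      i1 <- substr(bits, 1, 1) == "1"
      i2 <- substr(bits, 2, 2) == "1"
      parts <- c(internals[[g]],
                 if (i1) "r11", if (i2) "r12",
                 "r10")
      tibble(strain = paste0(g, bits), grna = parts)
    })
  })
  bind_rows(rows, tibble(strain = "NOR00", grna = c("r6", "r10")))
}

# Reads per strain: random background with each designed gRNA (or, for
# injected "add" anomalies, an undesigned one) embedded in one read; "drop"
# anomalies leave the designed gRNA out. Returns the reads and the presence
# ground truth the results matrix must reproduce.
simulate_reads <- function(strains, lib, cfg) {
  rd <- cfg$reads
  anomalies <- cfg$dnaseq_anomalies %||%
    tibble(strain = character(), grna = character(), type = character())
  seq_by_name <- setNames(lib$sequence, lib$grna)

  sequenced <- strains  # WT included: its empty part list yields an all-zero row
  reads <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(sequenced))) {
    s <- sequenced$strain[i]
    designed <- sequenced$grnas[[i]]
    drops <- filter(anomalies, .data$strain == s, .data$type == "drop")$grna
    adds <- filter(anomalies, .data$strain == s, .data$type == "add")$grna
    present <- union(setdiff(designed, drops), adds)
    present <- intersect(present, lib$grna)
    rs <- with_seed(substream_seed(cfg$seed, paste0("reads/", s)), {
      base <- vapply(seq_len(rd$n_per_strain), function(j) {
        paste(sample(c("A", "C", "G", "T"), rd$length, replace = TRUE), collapse = "")
      }, character(1))
      if (length(present) > 0) {
        slots <- sample.int(rd$n_per_strain, length(present),
                            replace = length(present) > rd$n_per_strain)
        for (k in seq_along(present)) {
          g <- seq_by_name[[present[k]]]
          pos <- sample.int(rd$length - nchar(g) + 1L, 1L)
          r <- base[slots[k]]
          substr(r, pos, pos + nchar(g) - 1L) <- g
          # embed reverse complement for every other insertion
          if (k %% 2L == 0L) {
            r <- base[slots[k]]
            rc <- revcomp(g)
            substr(r, pos, pos + nchar(rc) - 1L) <- rc
          }
          base[slots[k]] <- r
        }
      }
      base
    })
    reads[[s]] <- rs
    truth_rows[[s]] <- tibble(strain = s, grna = lib$grna,
                              present = as.integer(lib$grna %in% present))
  }
  list(reads = reads, truth_presence = bind_rows(truth_rows))
}

#' Write a synthetic campaign to plain-text files
#'
#' Event tables as one CSV per well, layout / plate reader / ground truth
#' as TSV, reads as FASTA (one file per strain), the gRNA library as TSV
#' and the configuration as YAML.
#'
#' @param campaign a [simulate_campaign()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "events"), showWarnings = FALSE)
  for (w in unique(campaign$events$well_id)) {
    utils::write.csv(filter(campaign$events, .data$well_id == w),
                     file.path(dir, "events", paste0(w, ".csv")),
                     row.names = FALSE)
  }
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          row.names = FALSE, quote = FALSE)
  wt(campaign$layout[setdiff(names(campaign$layout), "grnas")], "layout.tsv")
  wt(campaign$plate_reader, "plate_reader.tsv")
  wt(campaign$truth$wells, "truth_wells.tsv")
  wt(campaign$truth$results, "truth_presence.tsv")
  wt(campaign$grna_library, "grna_library.tsv")
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  for (s in names(campaign$reads)) {
    seqs <- Biostrings::DNAStringSet(campaign$reads[[s]])
    names(seqs) <- paste0(s, "_read", seq_along(seqs))
    Biostrings::writeXStringSet(seqs, file.path(dir, "reads", paste0(s, ".fasta")))
  }
  cfg <- campaign$config
  yaml::write_yaml(
    list(seed = cfg$seed, n_replicates = cfg$n_replicates,
         events_per_well = cfg$events_per_well,
         saturation_limit = cfg$saturation_limit),
    file.path(dir, "config.yaml")
  )
  invisible(dir)
}
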