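# Sequence verification of circuit builds: exact gRNA matching in reads,
# design vs results presence matrices, anomaly classification, and design
# compatibility.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_grna_seq <- function(grna) {
  if (!grepl("^[ACGT]+$", grna)) {
    abort("gRNA sequence must be non-empty A/C/G/T text",
          class = "gatescore_dnaseq_error")
  }
}

#' Exact-match search for a gRNA in sequencing reads
#'
#' A hit (1) means at least `min_reads` reads contain the gRNA sequence
#' *or its reverse complement* as an exact substring. Matching is strict:
#' ambiguous bases (N) in reads never match, and no mismatches are
#' tolerated — coding sequences and target sites share the same DNA
#' sequence, so a hit cannot distinguish the two roles.
#'
#' @param reads character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param grna a single gRNA DNA sequence (A/C/G/T).
#' @param min_reads minimum number of matching reads for a hit; default 1.
#' @return Integer 0 or 1.
#' @examples
#' search_grna(c("TTACGTACGTTT"), "ACGTACGT") # 1
#' @export
search_grna <- function(reads, grna, min_reads = 1L) {
  check_grna_seq(grna)
  subject <- if (inherits(reads, "DNAStringSet")) reads else {
    Biostrings::DNAStringSet(as.character(reads))
  }
  if (length(subject) == 0) return(0L)
  # a read counts once even if it carries both orientations
  hits <- sum(Biostrings::vcountPattern(grna, subject, fixed = TRUE) +
                Biostrings::vcountPattern(revcomp(grna), subject, fixed = TRUE) > 0)
  as.integer(hits >= min_reads)
}

#' Results matrix: observed gRNA presence per strain
#'
#' Runs [search_grna()] for every strain x gRNA pair. Strains without a
#' read set are *flagged absent* (`NA` cells), never silently zero-filled
#' — an absent dataset is not evidence of an absent sequence.
#'
#' @param reads_by_strain named list of read vectors, one element per
#'   strain.
#' @param library gRNA library tibble with columns `grna`, `sequence`.
#' @param strains optional strain labels expected to be present; defaults
#'   to the names of `reads_by_strain`.
#' @param min_reads minimum matching reads for a hit.
#' @return A long presence tibble: `strain`, `grna`, `present` (0/1, `NA`
#'   for missing read sets), with attribute `role = "results"`.
#' @export
build_results_matrix <- function(reads_by_strain, library,
                                 strains = names(reads_by_strain),
                                 min_reads = 1L) {
  stopifnot(all(c("grna", "sequence") %in% names(library)))
  missing <- setdiff(strains, names(reads_by_strain))
  if (length(missing) > 0) {
    warn(paste0("no read set for strain(s): ", paste(missing, collapse = ", "),
                "; their rows are flagged NA"))
  }
  out <- purrr::map_dfr(strains, function(s) {
    if (!s %in% names(reads_by_strain)) {
      return(tibble(strain = s, grna = library$grna, present = NA_integer_))
    }
    subject <- Biostrings::DNAStringSet(as.character(reads_by_strain[[s]]))
    tibble(
      strain = s, grna = library$grna,
      present = vapply(library$sequence, function(g) {
        search_grna(subject, g, min_reads = min_reads)
      }, integer(1), USE.NAMES = FALSE)
    )
  })
  attr(out, "role") <- "results"
  out
}

#' Design matrix: expected gRNA presence per strain
#'
#' Cell (s, g) is 1 iff strain s's design contains gRNA g as a coding
#' sequence *or* a target site — raw-read matching cannot tell the roles
#' apart, so the design matrix ORs them. Every part named in a design must
#' exist in the library.
#'
#' @param strains strain tibble with `strain` and a `grnas` list-column
#'   (see [strain_panel()]).
#' @param library gRNA library tibble.
#' @return A long presence tibble (`strain`, `grna`, `present`) with
#'   attribute `role = "design"`.
#' @export
build_design_matrix <- function(strains, library) {
  stopifnot("grnas" %in% names(strains))
  unknown <- setdiff(unique(unlist(strains$grnas)), library$grna)
  if (length(unknown) > 0) {
    abort(paste0("design names gRNA(s) absent from the library: ",
                 paste(unknown, collapse = ", ")),
          class = "gatescore_dnaseq_error")
  }
  out <- purrr::map2_dfr(strains$strain, strains$grnas, function(s, parts) {
    tibble(strain = s, grna = library$grna,
           present = as.integer(library$grna %in% parts))
  })
  attr(out, "role") <- "design"
  out
}

#' Classify design-vs-results anomalies
#'
#' Joins the design and results presence tibbles cell-wise and classifies
#' each cell: `expected` when they agree; `unexpected_absence` when the
#' design requires a gRNA the reads lack (a build error — or poor
#' sequencing coverage); `unexpected_presence` when the reads carry a gRNA
#' the design excludes (a mislabeled sample, wrong design record, or
#' cross-contamination — the stronger predictor of real trouble). Cells
#' with `NA` results (missing read set) classify as `no_data`.
#'
#' @param design,results long presence tibbles over identical strain and
#'   gRNA sets.
#' @return List of class `grna_anomalies`: `cells` (long tibble with
#'   `status`), `by_strain` and `by_grna` anomaly counts, `n_anomalies`.
#' @export
find_anomalies <- function(design, results) {
  key_d <- paste(design$strain, design$grna)
  key_r <- paste(results$strain, results$grna)
  if (!setequal(key_d, key_r) || length(key_d) != length(key_r)) {
    abort("design and results matrices must share rows and columns",
          class = "gatescore_dnaseq_error")
  }
  cells <- inner_join(
    rename(design, design = "present"),
    rename(results, observed = "present"),
    by = c("strain", "grna")
  ) |>
    mutate(status = dplyr::case_when(
      is.na(.data$observed) ~ "no_data",
      .data$design == 1L & .data$observed == 0L ~ "unexpected_absence",
      .data$design == 0L & .data$observed == 1L ~ "unexpected_presence",
      TRUE ~ "expected"
    ))
  anom <- filter(cells, .data$status %in% c("unexpected_absence",
                                            "unexpected_presence"))
  structure(
    list(
      cells = cells,
      by_strain = cells |>
        group_by(.data$strain) |>
        summarise(
          n_unexpected_absence = sum(.data$status == "unexpected_absence"),
          n_unexpected_presence = sum(.data$status == "unexpected_presence"),
          .groups = "drop"
        ),
      by_grna = cells |>
        group_by(.data$grna) |>
        summarise(
          n_unexpected_absence = sum(.data$status == "unexpected_absence"),
          n_unexpected_presence = sum(.data$status == "unexpected_presence"),
          .groups = "drop"
        ),
      n_anomalies = nrow(anom)
    ),
    class = "grna_anomalies"
  )
}

#' @export
print.grna_anomalies <- function(x, ...) {
  cat("<grna_anomalies> ", x$n_anomalies, " anomalous cell(s) of ",
      nrow(x$cells), "\n", sep = "")
  if (x$n_anomalies > 0) {
    print(filter(x$cells, .data$status != "expected"))
  }
  invisible(x)
}

#' Tidy / glance methods for anomaly classifications
#'
#' @param x a `grna_anomalies` object.
#' @param ... unused.
#' @return `tidy()`: the cell-level tibble with `status`; `glance()`: one
#'   row of totals.
#' @method tidy grna_anomalies
#' @export
tidy.grna_anomalies <- function(x, ...) x$cells

#' @rdname tidy.grna_anomalies
#' @method glance grna_anomalies
#' @export
glance.grna_anomalies <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    n_unexpected_absence = sum(x$cells$status == "unexpected_absence"),
    n_unexpected_presence = sum(x$cells$status == "unexpected_presence"),
    n_no_data = sum(x$cells$status == "no_data"),
    n_anomalies = x$n_anomalies
  )
}

#' Which candidate designs are compatible with an observed gRNA row?
#'
#' A candidate design is compatible when every gRNA it requires is
#' observed present. With `strict = TRUE`, observed gRNAs the design does
#' *not* require also disqualify it (useful when contamination can be
#' ruled out); by default extra presences are ignored, since absences of
#' non-required parts carry no information about the build.
#'
#' @param observed named 0/1 vector (names are gRNA names) or a one-strain
#'   long presence tibble.
#' @param candidates strain/design tibble with `strain` and `grnas`
#'   list-column.
#' @param strict disqualify designs lacking an observed gRNA.
#' @return Character vector of compatible candidate labels (possibly
#'   empty).
#' @export
design_compatibility <- function(observed, candidates, strict = FALSE) {
  if (is.data.frame(observed)) {
    observed <- setNames(observed$present, observed$grna)
  }
  present <- names(observed)[!is.na(observed) & observed == 1L]
  if (nrow(candidates) == 0) return(character(0))
  ok <- purrr::map2_lgl(candidates$strain, candidates$grnas, function(s, req) {
    if (!all(req %in% present)) return(FALSE)
    if (strict && !all(present %in% req)) return(FALSE)
    TRUE
  })
  candidates$strain[ok]
}

#' Fold-coverage estimate per strain
#'
#' Total sequenced bases divided by genome size — the coarse check that a
#' missing gRNA feature is not simply explained by an inadequate read
#' count (it assumes uniform coverage, which raw totals cannot verify).
#'
#' @param reads_by_strain named list of read vectors.
#' @param genome_size genome length in bases.
#' @return Tibble: `strain`, `total_bases`, `coverage`.
#' @export
coverage_estimate <- function(reads_by_strain, genome_size) {
  stopifnot(genome_size > 0)
  purrr::imap_dfr(reads_by_strain, function(rs, s) {
    tb <- sum(nchar(as.character(rs)))
    tibble(strain = s, total_bases = tb, coverage = tb / genome_size)
  })
}

#' Read sequencing reads from FASTA/FASTQ files
#'
#' @param paths named character vector of file paths; names are strain
#'   labels (defaults to file names sans extension).
#' @param format `"fasta"` or `"fastq"`; inferred from the first file's
#'   extension when `NULL`.
#' @return Named list of character vectors of read sequences.
#' @export
read_strain_reads <- function(paths, format = NULL) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.(fa|fasta|fq|fastq)(\\.gz)?$", "",
                        basename(paths), ignore.case = TRUE)
  }
  if (is.null(format)) {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", paths[1], ignore.case = TRUE)) {
      "fastq"
    } else "fasta"
  }
  purrr::map(as.list(paths), function(p) {
    as.character(Biostrings::readDNAStringSet(p, format = format))
  })
}

#' Read a gRNA library from FASTA or TSV
#'
#' @param path a FASTA file (names become gRNA names) or a TSV with
#'   columns `grna` and `sequence`.
#' @return Tibble: `grna`, `sequence`.
#' @export
read_grna_library <- function(path) {
  if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    tibble(grna = names(ss), sequence = unname(as.character(ss)))
  } else {
    as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE))
  }
}
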