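#' @importFrom rlang .data abort warn .env
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   left_join inner_join bind_rows n across rename count distinct pull if_else
#' @importFrom stats setNames
NULL

GATE_NAMES <- c("AND", "OR", "NAND", "NOR", "XOR", "XNOR")

gate_fun <- function(name) {
  switch(name,
    AND  = function(a, b) a & b,
    OR   = function(a, b) a | b,
    NAND = function(a, b) !(a & b),
    NOR  = function(a, b) !(a | b),
    XOR  = function(a, b) xor(a, b),
    XNOR = function(a, b) !xor(a, b),
    abort(paste0("unknown gate name: '", name, "'"), class = "gatescore_gate_error")
  )
}

#' Truth tables for the six two-input logic gates
#'
#' One row per gate and input pair: the complete Boolean semantics of the
#' AND, OR, NAND, NOR, XOR and XNOR gates implemented as CRISPR-dCas9
#' NOR-gate circuits in yeast.
#'
#' @param gates character vector of gate names; defaults to all six.
#' @return A tibble with columns `gate`, `input1`, `input2`, `output`
#'   (all inputs/outputs are 0/1 integers).
#' @examples
#' gate_truth_tables("NOR")
#' @export
gate_truth_tables <- function(gates = GATE_NAMES) {
  gates <- toupper(gates)
  bad <- setdiff(gates, GATE_NAMES)
  if (length(bad) > 0) {
    abort(paste0("unknown gate name: '", bad[1], "'"), class = "gatescore_gate_error")
  }
  grid <- tidyr::expand_grid(
    gate = gates,
    input1 = 0:1,
    input2 = 0:1
  )
  mutate(grid,
    output = as.integer(purrr::pmap_lgl(
      list(.data$gate, .data$input1, .data$input2),
      function(g, a, b) gate_fun(g)(a == 1L, b == 1L)
    ))
  )
}

#' Expected output bit of a gate for an input pair
#'
#' @param gate gate name, one of AND, OR, NAND, NOR, XOR, XNOR.
#' @param input1,input2 input bits, each 0 or 1.
#' @return 0 or 1 (integer).
#' @examples
#' expected_output("NOR", 0, 0) # 1: the NOR00 strain is the high control
#' @export
expected_output <- function(gate, input1, input2) {
  stopifnot(all(input1 %in% 0:1), all(input2 %in% 0:1))
  out <- mapply(function(g, a, b) {
    as.integer(gate_fun(toupper(g))(a == 1L, b == 1L))
  }, gate, input1, input2, USE.NAMES = FALSE)
  as.integer(out)
}

#' Parse a strain label into its circuit specification
#'
#' Experimental strains are named `<GATE><input1><input2>` (e.g. `"OR01"`
#' is the OR gate strain holding inputs 0 and 1; the character right after
#' the gate name is input 1). Two control labels are recognized: `"WT"`,
#' the non-fluorescent wild-type negative control (expected low), and
#' `"NOR00"`, which doubles as the constitutively-high positive control.
#'
#' @param label character vector of strain labels.
#' @return A tibble with one row per label: `strain`, `gate`, `input1`,
#'   `input2`, `expected_output`, `is_control`, `control_role` (`"positive"`,
#'   `"negative"` or `NA`).
#' @examples
#' parse_strain_label(c("OR01", "WT", "AND10"))
#' @export
parse_strain_label <- function(label) {
  parse_one <- function(lab) {
    if (identical(lab, "WT")) {
      return(tibble(
        strain = "WT", gate = NA_character_,
        input1 = NA_integer_, input2 = NA_integer_,
        expected_output = 0L, is_control = TRUE, control_role = "negative"
      ))
    }
    m <- regmatches(lab, regexec("^(AND|OR|NAND|NOR|XOR|XNOR)([01])([01])$", lab))[[1]]
    if (length(m) == 0) {
      abort(paste0("cannot parse strain label: '", lab, "'"),
            class = "gatescore_label_error")
    }
    gate <- m[2]
    i1 <- as.integer(m[3])
    i2 <- as.integer(m[4])
    tibble(
      strain = lab, gate = gate, input1 = i1, input2 = i2,
      expected_output = expected_output(gate, i1, i2),
      is_control = identical(lab, "NOR00"),
      control_role = if (identical(lab, "NOR00")) "positive" else NA_character_
    )
  }
  purrr::map_dfr(label, parse_one)
}

#' Specifications for the full experimental strain panel
#'
#' The 24 experimental strains (6 gates x 4 input states) plus the WT and
#' NOR00 controls, with expected outputs and gRNA part lists. gRNA part
#' names come from a library specification: since the circuits' real part
#' lists are proprietary to the original designs, the default is the
#' synthetic library layout from [synthetic_grna_parts()].
#'
#' @param parts optional tibble with columns `strain`, `grna` giving each
#'   strain's gRNA parts (coding sequences and target sites share names);
#'   defaults to [synthetic_grna_parts()].
#' @return A tibble with columns `strain`, `gate`, `input1`, `input2`,
#'   `expected_output`, `is_control`, `control_role`, and a list-column
#'   `grnas` of part names.
#' @export
strain_panel <- function(parts = synthetic_grna_parts()) {
  labels <- c(
    paste0(rep(GATE_NAMES, each = 4), rep(c("00", "01", "10", "11"), 6)),
    "WT"
  )
  specs <- parse_strain_label(labels)
  part_list <- split(parts$grna, parts$strain)
  specs$grnas <- purrr::map(specs$strain, ~ unname(part_list[[.x]] %||% character(0)))
  specs
}

#' Growth-condition parameter set
#'
#' The four protocol parameters controlling the growth phase: incubation
#' temperature (30 or 37 C), overnight incubation hours (8-18, default 16),
#' growth medium (synthetic complete by default) and the target optical
#' density at inoculation.
#'
#' @param temperature_C incubation temperature in degrees Celsius.
#' @param overnight_hours overnight incubation duration in hours.
#' @param medium growth medium, one of `"SC"`, `"rich"`, `"slow"`,
#'   `"high_osmolarity"`.
#' @param target_od target optical density (OD units) after dilution.
#' @return A one-row tibble of the validated condition.
#' @examples
#' growth_condition() # the standard conditions
#' @export
growth_condition <- function(temperature_C = 30,
                             overnight_hours = 16,
                             medium = c("SC", "rich", "slow", "high_osmolarity"),
                             target_od = 0.0003) {
  medium <- match.arg(medium)
  if (!temperature_C %in% c(30, 37)) {
    abort("temperature_C must be 30 or 37", class = "gatescore_condition_error")
  }
  if (overnight_hours < 8 || overnight_hours > 18) {
    abort("overnight_hours must be in [8, 18]", class = "gatescore_condition_error")
  }
  if (target_od <= 0) {
    abort("target_od must be positive", class = "gatescore_condition_error")
  }
  tibble(
    temperature_C = temperature_C,
    overnight_hours = overnight_hours,
    medium = medium,
    target_od = target_od
  )
}

#' Load strain/circuit specifications from a YAML or JSON file
#'
#' Expects a top-level list `strains`, each entry with fields `label` and
#' optionally `grnas` (character vector of part names). Gate, inputs and
#' expected output are derived from the label.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A tibble shaped like [strain_panel()].
#' @export
read_circuit_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- raw$strains %||% raw
  specs <- purrr::map_dfr(entries, function(e) {
    s <- parse_strain_label(e$label)
    s$grnas <- list(as.character(unlist(e$grnas %||% character(0))))
    s
  })
  specs
}

`%||%` <- function(x, y) if (is.null(x)) y else x
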