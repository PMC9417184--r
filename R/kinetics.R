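# Derived quantities from measured RuBisCO kinetic parameters. The
# specificity factor S_C/O = (V_C/K_C)/(V_O/K_O) links the carboxylase and
# oxygenase turnover numbers (per-active-site V = kcat), so an unmeasured
# oxygenase turnover can be recovered from the other four parameters.

#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Oxygenase turnover from the specificity relation
#'
#' Inverts `S_C/O = (kcat_C / K_C) / (kcat_O / K_O)` to
#' `kcat_O = kcat_C * K_O / (S_C/O * K_C)`. Full precision is kept; round at
#' report time only.
#'
#' @param kcat_c Carboxylase turnover, 1/s.
#' @param k_c Michaelis constant for CO2, uM.
#' @param s_co Dimensionless specificity factor.
#' @param k_o Michaelis constant for O2, uM.
#' @return kcat_O in 1/s.
#' @export
#' @examples
#' kcat_o_from_specificity(15.7, 172, 22.0, 92) # 0.3817 -> prints as 0.38
kcat_o_from_specificity <- function(kcat_c, k_c, s_co, k_o) {
  vals <- c(kcat_c, k_c, s_co, k_o)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all kinetic parameters must be positive")
  }
  kcat_c * k_o / (s_co * k_c)
}

#' Mutant-over-wild-type fold change
#'
#' @param mutant_value,wildtype_value Positive parameter values.
#' @return The ratio `mutant / wildtype`, full precision.
#' @export
fold_change <- function(mutant_value, wildtype_value) {
  if (any(wildtype_value == 0)) stop("wild-type value must be non-zero")
  mutant_value / wildtype_value
}

#' Percent decrease relative to the wild type
#'
#' @param mutant_value,wildtype_value Parameter values; wild type non-zero.
#' @return `(1 - mutant/wildtype) * 100`, full precision.
#' @export
percent_decrease <- function(mutant_value, wildtype_value) {
  if (any(wildtype_value == 0)) stop("wild-type value must be non-zero")
  (1 - mutant_value / wildtype_value) * 100
}

#' Read a kinetics table from TSV
#'
#' Expected header: `enzyme`, `state`, `kcat_c`, `k_c`, `s_co`, `k_o` and
#' optionally `kcat_o` (measured).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_kinetics <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
  names(tb) <- tolower(names(tb))
  required <- c("enzyme", "state", "kcat_c", "k_c", "s_co", "k_o")
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols)) {
    stop("kinetics table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tb
}

#' Derived kinetics report
#'
#' For every enzyme row, derives the oxygenase turnover from the specificity
#' relation (unless a measured `kcat_o` is present, which is kept and
#' flagged), and computes fold changes of `s_co` and `k_o` and the percent
#' decrease of `kcat_c` relative to the reference enzyme. Values are held at
#' full precision in `*_raw` columns and rounded half-up to the printed
#' precision (2 decimals for ratios and turnovers, whole percent for
#' decreases) in the display columns.
#'
#' @param records Tibble as returned by [read_kinetics()].
#' @param reference Enzyme label of the reference (e.g. the wild type).
#' @return A tibble with one row per enzyme and derived columns.
#' @export
#' @examples
#' tb <- tibble::tibble(
#'   enzyme = c("wild-type", "R98A"), state = c("L6", "L2"),
#'   kcat_c = c(15.7, 11.1), k_c = c(172, 170),
#'   s_co = c(22.0, 25.7), k_o = c(92, 155)
#' )
#' kinetics_table(tb, "wild-type")
kinetics_table <- function(records, reference) {
  records <- tibble::as_tibble(records)
  if (!reference %in% records$enzyme) stop("reference enzyme not found: ", reference)
  ok <- stats::complete.cases(records[, c("kcat_c", "k_c", "s_co", "k_o")])
  if (any(!ok)) {
    warning("skipping rows with missing kinetic parameters: ",
            paste(records$enzyme[!ok], collapse = ", "))
    records <- records[ok, , drop = FALSE]
  }
  ref <- records[records$enzyme == reference, ]
  kcat_o_meas <- records[["kcat_o"]] %||% rep(NA_real_, nrow(records))
  derived <- is.na(kcat_o_meas)
  kcat_o_raw <- ifelse(
    derived,
    kcat_o_from_specificity(records$kcat_c, records$k_c, records$s_co, records$k_o),
    kcat_o_meas
  )
  out <- tibble::tibble(
    enzyme = records$enzyme,
    state = records$state,
    kcat_c = records$kcat_c, k_c = records$k_c,
    s_co = records$s_co, k_o = records$k_o,
    kcat_o_raw = kcat_o_raw,
    kcat_o = round_half_up(kcat_o_raw, 2),
    kcat_o_derived = derived,
    s_co_fold_raw = fold_change(records$s_co, ref$s_co),
    s_co_fold = round_half_up(fold_change(records$s_co, ref$s_co), 2),
    k_o_fold_raw = fold_change(records$k_o, ref$k_o),
    k_o_fold = round_half_up(fold_change(records$k_o, ref$k_o), 2),
    kcat_c_decrease_raw = percent_decrease(records$kcat_c, ref$kcat_c),
    kcat_c_decrease_pct = round_half_up(percent_decrease(records$kcat_c, ref$kcat_c), 0)
  )
  attr(out, "reference") <- reference
  out
}
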