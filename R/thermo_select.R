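# Thermodynamic selection and detection: hydrogen-bond counting, GC-based
# melting-temperature estimation, melting-curve synthesis with derivative
# peak calling, Tm-shift genotyping, and denaturation-gradient (3D-PCR
# style) selection of AT-rich sequences.
#
# Tm model (Marmur-Schildkraut with salt and length terms):
#   Tm = 81.5 + 16.6 * log10([Na+]) + 0.41 * GC% - 675 / length
# Every CG>TA transition in a window of length L therefore lowers Tm by
# exactly 0.41 * (100 / L) degC; all screening logic here is relative
# (shifts and orderings), never an absolute instrument calibration.

#' Thermodynamic model parameters
#'
#' @param na_molar Monovalent cation concentration in mol/L (default 0.05).
#' @param sigmoid_width Two-state transition width of the melt sigmoid, degC
#'   (default 0.3).
#' @param delta_tm_threshold Minimum Tm drop below the wild type to call a
#'   sample mutant, degC (default 0.4, just under the smallest wild-type vs
#'   mutant gap seen in RAS screening, 0.5 degC).
#' @return Object of class `thermo_params`.
#' @export
thermo_params <- function(na_molar = 0.05, sigmoid_width = 0.3,
                          delta_tm_threshold = 0.4) {
  assert_scalar_number(na_molar, "na_molar", lower = 1e-12)
  assert_scalar_number(sigmoid_width, "sigmoid_width", lower = 1e-12)
  assert_scalar_number(delta_tm_threshold, "delta_tm_threshold", lower = 0)
  structure(list(na_molar = na_molar, sigmoid_width = sigmoid_width,
                 delta_tm_threshold = delta_tm_threshold),
            class = "thermo_params")
}

#' Hydrogen bonds of a perfect duplex
#'
#' Interpreting the sequence as one strand of a perfect duplex: G:C pairs
#' contribute 3 hydrogen bonds, A:T pairs 2, so a single CG>TA transition
#' loses exactly one bond. Additive over concatenation.
#'
#' @param seq ACGT sequence (string or `nucleotide_sequence`).
#' @return Integer bond count.
#' @export
#' @examples
#' hydrogen_bond_count("GC") # 6
#' hydrogen_bond_count("AT") # 4
hydrogen_bond_count <- function(seq) {
  idx <- seq_to_int(as_bases(seq))
  gc <- sum(idx == 2L | idx == 3L)
  3L * gc + 2L * (length(idx) - gc)
}

#' G+C percentage of a sequence
#'
#' @param seq ACGT sequence.
#' @return Percentage in `[0, 100]`.
#' @export
gc_percent <- function(seq) {
  idx <- seq_to_int(as_bases(seq))
  100 * sum(idx == 2L | idx == 3L) / length(idx)
}

#' GC-content melting-temperature estimate
#'
#' `Tm = 81.5 + 16.6 log10(na_molar) + 0.41 GC% - 675/L`. Strictly
#' increasing in GC% at fixed length and salt; one CG>TA transition in a
#' window of length `L` lowers Tm by exactly `0.41 * 100 / L` degC.
#'
#' @param seq ACGT sequence of length >= 14 (the formula's validity floor;
#'   shorter probes would need a nearest-neighbor model).
#' @param params A [thermo_params()].
#' @return Tm in degC.
#' @export
tm_estimate <- function(seq, params = thermo_params()) {
  bases <- as_bases(seq)
  L <- nchar(bases)
  if (L < 14)
    stop("tm_estimate requires length >= 14; use a nearest-neighbor model for short probes")
  81.5 + 16.6 * log10(params$na_molar) + 0.41 * gc_percent(bases) - 675 / L
}

#' Synthesize a melting profile from a species mixture
#'
#' Fluorescence is a weighted sum of two-state sigmoids,
#' `F(T) = sum_i w_i * logistic((Tm_i - T) / sigmoid_width)`; the negative
#' derivative is computed by central differences on the grid and the called
#' Tm is its argmax (no interpolation).
#'
#' @param species Data frame (or two-column matrix) with columns `weight`
#'   and `tm`; weights >= 0 summing to 1.
#' @param params A [thermo_params()].
#' @param temps Temperature grid, degC, strictly increasing; default spans
#'   all species Tms plus a 5 degC margin at 0.1 degC steps.
#' @return Object of class `melting_profile`: list with `temps`,
#'   `fluorescence`, `derivative` (-dF/dT) and `tm_called`.
#' @export
melt_curve <- function(species, params = thermo_params(), temps = NULL) {
  species <- as.data.frame(species)
  if (!nrow(species)) stop("empty species list")
  if (is.null(species$weight) || is.null(species$tm))
    stop("'species' needs columns 'weight' and 'tm'")
  if (any(species$weight < 0) || abs(sum(species$weight) - 1) > 1e-8)
    stop("weights must be >= 0 and sum to 1")
  if (is.null(temps))
    temps <- seq(min(species$tm) - 5, max(species$tm) + 5, by = 0.1)
  if (length(temps) < 3 || any(diff(temps) <= 0))
    stop("'temps' must be a strictly increasing grid of length >= 3")
  if (min(temps) > min(species$tm) || max(temps) < max(species$tm))
    stop("temperature grid must span all species Tms")
  fl <- colSums(species$weight *
                  stats::plogis(outer(species$tm, temps, `-`) / params$sigmoid_width))
  n <- length(temps)
  deriv <- c(-(fl[2] - fl[1]) / (temps[2] - temps[1]),
             -(fl[3:n] - fl[1:(n - 2)]) / (temps[3:n] - temps[1:(n - 2)]),
             -(fl[n] - fl[n - 1]) / (temps[n] - temps[n - 1]))
  structure(list(temps = temps, fluorescence = fl, derivative = deriv,
                 tm_called = temps[which.max(deriv)]),
            class = "melting_profile")
}

#' @export
print.melting_profile <- function(x, ...) {
  cat(sprintf("<melting_profile> %d points, %.1f-%.1f degC, Tm called %.2f degC\n",
              length(x$temps), min(x$temps), max(x$temps), x$tm_called))
  invisible(x)
}

#' Call a sample wild type or mutant from its melting profile
#'
#' A sample is mutant when its called Tm sits at least
#' `delta_tm_threshold` degC below the wild-type Tm (hydrogen-bond loss of a
#' CG>TA transition melts the duplex earlier).
#'
#' @param sample A [melt_curve()] profile, or a numeric called Tm.
#' @param wt_tm Wild-type reference Tm, degC.
#' @param params A [thermo_params()].
#' @return `"mutant"` or `"WT"`.
#' @export
classify_sample <- function(sample, wt_tm, params = thermo_params()) {
  tm <- if (inherits(sample, "melting_profile")) sample$tm_called
        else assert_scalar_number(sample, "sample")
  if (wt_tm - tm >= params$delta_tm_threshold) "mutant" else "WT"
}

#' Denaturation-gradient selection of AT-rich sequences
#'
#' Differential-denaturation selection: a sequence's denaturation
#' temperature Td is its [tm_estimate()]; it is recovered at a gradient
#' temperature T iff `Td <= T`, so recovered sets are nested non-decreasing
#' in T and AT-richer (CG>TA-loaded) sequences appear at lower temperatures.
#'
#' @param seqs Named character vector or list of sequences (names become
#'   ids; unnamed inputs get `seq1..n`).
#' @param gradient Numeric vector of denaturation temperatures, degC.
#' @param params A [thermo_params()].
#' @param soft_width Optional logistic soft margin, degC: when non-`NULL`, a
#'   sequence is recovered with probability
#'   `logistic((T - Td)/soft_width)` instead of the hard step; requires
#'   `seed` for reproducibility.
#' @param seed Seed for the soft-margin draw.
#' @return Object of class `selection_result`: list with `td` (named per-
#'   sequence Td) and `recovered` (named list, per gradient temperature, of
#'   recovered sequence ids).
#' @export
td_selection <- function(seqs, gradient, params = thermo_params(),
                         soft_width = NULL, seed = NULL) {
  if (!length(gradient)) stop("'gradient' must be non-empty")
  seqs <- as.list(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(seqs))
  td <- vapply(seqs, function(s) tm_estimate(as_bases(s), params), numeric(1))
  names(td) <- ids
  gradient <- sort(gradient)
  recovered <- if (is.null(soft_width)) {
    lapply(gradient, function(temp) ids[td <= temp])
  } else {
    # a draw per sequence, shared across temperatures, preserves nestedness
    u <- with_seed(seed, runif(length(ids)))
    lapply(gradient, function(temp)
      ids[u < stats::plogis((temp - td) / soft_width)])
  }
  names(recovered) <- sprintf("%.6g", gradient)
  structure(list(td = td, recovered = recovered, gradient = gradient),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d sequences over gradient %s degC\n",
              length(x$td), paste(sprintf("%.4g", x$gradient), collapse = ", ")))
  for (i in seq_along(x$recovered))
    cat(sprintf("  %s degC: %d recovered\n", names(x$recovered)[i],
                length(x$recovered[[i]])))
  invisible(x)
}
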