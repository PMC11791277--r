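# Synthetic-data generators: reference sequences, amplicon read sets,
# base-composition pairs, and patient cohorts with paired tumor/healthy
# melting temperatures. Every generator is a pure function of its arguments
# including the seed, so downstream analyses can be tested against known
# ground truth.

# Hotspot codon template mirroring the RAS coding frame: codon 11 = GCC,
# 12 = GGC, 13 = GGT, 23 = CTG, 61 = CAG, i.e. nt 31-33, 34-36, 37-39,
# 67-69, 181-183 of the CDS.
HOTSPOT_TEMPLATE <- list(`11` = "GCC", `12` = "GGC", `13` = "GGT",
                         `23` = "CTG", `61` = "CAG")

#' Specification for a synthetic reference sequence
#'
#' @param length Sequence length in nucleotides.
#' @param gc_target Desired G+C fraction in `[0, 1]`.
#' @param hotspot_template If `TRUE`, fix codons 11, 12, 13, 23 and 61 to the
#'   RAS-like codons GCC, GGC, GGT, CTG and CAG (nt 31-33, 34-36, 37-39,
#'   67-69, 181-183); requires `length >= 183`.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(length, gc_target = 0.5, hotspot_template = FALSE,
                           seed = NULL) {
  assert_scalar_number(length, "length", lower = 1)
  assert_scalar_number(gc_target, "gc_target", lower = 0, upper = 1)
  stopifnot(is.logical(hotspot_template), length(hotspot_template) == 1L)
  if (hotspot_template && length < 183)
    stop("hotspot_template requires length >= 183 (codon 61 spans nt 181-183)")
  structure(list(length = as.integer(length), gc_target = gc_target,
                 hotspot_template = hotspot_template, seed = seed),
            class = "reference_spec")
}

#' Generate a synthetic reference sequence
#'
#' Draws a random ACGT sequence hitting `gc_target` to within rounding on the
#' freely chosen positions. With `hotspot_template` the RAS-like hotspot
#' codons are placed at their canonical CDS positions (codon 12 at nt 34-36,
#' codon 13 at nt 37-39, codon 61 at nt 181-183); those positions are
#' excluded from the GC adjustment.
#'
#' @param spec A [reference_spec()], or a length (with the remaining
#'   arguments passed along).
#' @param ... Passed to [reference_spec()] when `spec` is a bare length.
#' @return A list of class `nucleotide_sequence` with elements `id` and
#'   `bases`.
#' @export
#' @examples
#' ref <- make_reference(reference_spec(183, hotspot_template = TRUE, seed = 7))
#' substr(ref$bases, 34, 36) # "GGC", the Gly12 codon
make_reference <- function(spec, ...) {
  if (!inherits(spec, "reference_spec")) spec <- reference_spec(spec, ...)
  n <- spec$length
  fixed <- integer(0)
  bases <- integer(n)
  if (spec$hotspot_template) {
    for (k in names(HOTSPOT_TEMPLATE)) {
      pos <- codon_range(as.integer(k))
      bases[pos] <- seq_to_int(HOTSPOT_TEMPLATE[[k]])
      fixed <- c(fixed, pos)
    }
  }
  free <- setdiff(seq_len(n), fixed)
  with_seed(spec$seed, {
    n_gc <- round(spec$gc_target * length(free))
    gc_pos <- if (n_gc > 0) sample(free, n_gc) else integer(0)
    at_pos <- setdiff(free, gc_pos)
    bases[gc_pos] <- sample(c(2L, 3L), length(gc_pos), replace = TRUE) # C/G
    bases[at_pos] <- sample(c(1L, 4L), length(at_pos), replace = TRUE) # A/T
  })
  out <- structure(list(id = sprintf("synthetic_ref_%dnt", n),
                        bases = int_to_seq(bases)),
                   class = "nucleotide_sequence")
  realized <- sum(bases %in% c(2L, 3L)) / n
  attr(out, "gc_realized") <- realized
  out
}

#' @export
print.nucleotide_sequence <- function(x, ...) {
  cat(sprintf("<nucleotide_sequence> %s (%d nt)\n", x$id, nchar(x$bases)))
  invisible(x)
}

# Coerce a nucleotide_sequence / character to a bare string of bases.
as_bases <- function(x) {
  if (inherits(x, "nucleotide_sequence")) x$bases
  else if (is.character(x) && length(x) == 1L) x
  else stop("expected a nucleotide_sequence or a single character string")
}

#' Simulate ungapped amplicon reads with a known substitution spectrum
#'
#' Reads are ungapped substrings of the reference (amplicon model: no
#' indels). Each base is substituted independently with probability given by
#' `rate` (a global scalar or a per-reference-position vector); the
#' alternative base is drawn from the `spectrum` row of the reference base.
#' Qualities are a constant Q37 placeholder.
#'
#' @param ref Reference sequence ([make_reference()] output or string).
#' @param rate Global substitution probability, or a numeric vector with one
#'   probability per reference position.
#' @param spectrum 4x4 matrix of conditional alternative-base probabilities
#'   (rows = reference base A,C,G,T; rows sum to 1 over the three
#'   off-diagonal entries; diagonal must be 0). Default: uniform over the
#'   three alternatives.
#' @param n_reads Number of reads.
#' @param read_len Read length (must not exceed the reference length).
#' @param seed Integer seed.
#' @return A `read_set`: list with `sequences`, `offsets` (1-based),
#'   `quality` (single Phred+33 character), and `truth` (the rate and
#'   spectrum used).
#' @export
simulate_reads <- function(ref, rate, spectrum = NULL, n_reads, read_len,
                           seed = NULL) {
  bases <- as_bases(ref)
  L <- nchar(bases)
  assert_scalar_number(n_reads, "n_reads", lower = 1)
  assert_scalar_number(read_len, "read_len", lower = 1, upper = L)
  if (!is.numeric(rate) || any(!is.finite(rate)) || any(rate < 0 | rate > 1))
    stop("'rate' probabilities must lie in [0, 1]")
  if (!(length(rate) %in% c(1L, L)))
    stop("'rate' must be a scalar or one value per reference position")
  if (is.null(spectrum)) {
    spectrum <- matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES))
    diag(spectrum) <- 0
  }
  spectrum <- as.matrix(spectrum)
  if (!all(dim(spectrum) == c(4L, 4L)) || any(spectrum < 0) ||
      any(diag(spectrum) != 0) || any(abs(rowSums(spectrum) - 1) > 1e-8))
    stop("'spectrum' rows must be probabilities over the three alternative bases summing to 1")

  refint <- seq_to_int(bases)
  n_reads <- as.integer(n_reads); read_len <- as.integer(read_len)
  cum <- t(apply(spectrum, 1, cumsum)) # 4x4 row-cumulative

  with_seed(seed, {
    offsets <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    # position matrix: n_reads x read_len of reference coordinates
    pos <- outer(offsets, 0:(read_len - 1L), `+`)
    obs <- matrix(refint[pos], n_reads, read_len)
    p <- if (length(rate) == 1L) rate else matrix(rate[pos], n_reads, read_len)
    hit <- which(runif(n_reads * read_len) < p)
    if (length(hit)) {
      rb <- obs[hit]
      u <- runif(length(hit))
      alt <- 1L + (u > cum[rb, 1L]) + (u > cum[rb, 2L]) + (u > cum[rb, 3L])
      obs[hit] <- alt
    }
  })
  chars <- charToRaw("ACGT")
  seqs <- vapply(seq_len(n_reads),
                 function(i) rawToChar(chars[obs[i, ]]), character(1))
  structure(list(sequences = seqs, offsets = offsets,
                 quality = "F", read_len = read_len,
                 truth = list(rate = rate, spectrum = spectrum)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads x %d nt (Q%d placeholder)\n",
              length(x$sequences), x$read_len,
              utf8ToInt(x$quality) - 33L))
  invisible(x)
}

#' Paired base compositions with a controlled A+T fold change
#'
#' Builds a treated composition whose A+T percentage is exactly
#' `fold_at` times the baseline's, with the G+C share filling the remainder
#' (G:C ratio preserved), so both vectors sum to 100 and
#' [at_enrichment()] on the pair recovers `fold_at` exactly.
#'
#' @param baseline Named percentage vector over A, C, G, T summing to 100.
#' @param fold_at Multiplicative change of the A+T percentage (> 0).
#' @return List with `before` and `after` [base_composition()] summaries.
#' @export
simulate_composition_pair <- function(baseline, fold_at) {
  assert_scalar_number(fold_at, "fold_at", lower = 1e-12)
  baseline <- baseline[BASES]
  if (anyNA(baseline) || abs(sum(baseline) - 100) > 1e-9)
    stop("'baseline' must be a named A/C/G/T percentage vector summing to 100")
  at0 <- baseline[["A"]] + baseline[["T"]]
  gc0 <- baseline[["C"]] + baseline[["G"]]
  at1 <- at0 * fold_at
  if (at1 > 100) stop("fold_at pushes the A+T percentage above 100%")
  after <- c(A = baseline[["A"]] * fold_at,
             C = if (gc0 > 0) baseline[["C"]] * (100 - at1) / gc0 else 0,
             G = if (gc0 > 0) baseline[["G"]] * (100 - at1) / gc0 else 0,
             T = baseline[["T"]] * fold_at)
  if (gc0 == 0 && fold_at != 1) stop("baseline has no G+C share to trade against")
  list(before = base_composition(baseline), after = base_composition(after))
}

#' Simulate a patient cohort with paired tumor/healthy melting temperatures
#'
#' Each patient contributes one tumor and one healthy row. Per gene, exactly
#' `round(n_patients * prevalence)` patients are mutant. Healthy tissue and
#' wild-type tumors melt at `tm_wt` plus Gaussian noise; tumors of patients
#' mutant in at least one gene melt `delta_tm_mut` degrees lower (the
#' hydrogen-bond-loss shift of a CG>TA transition).
#'
#' @param n_patients Number of patients (> 0).
#' @param prevalence Named per-gene mutant fractions in `[0, 1]`. Default
#'   mirrors a 135-patient colorectal screen: KRAS 39/135, BRAF 19/135,
#'   PI3K 16/135.
#' @param tm_wt Wild-type melting temperature (degC); default 78.7.
#' @param delta_tm_mut Tm decrease in mutant tumors (degC); default 1.3
#'   (78.7 - 77.4, the Gly12 vs Val12 gap).
#' @param noise_sd Gaussian measurement noise (degC).
#' @param seed Integer seed.
#' @return A `cohort_table` data frame with columns `patient_id`, `tissue`
#'   (`tumor`/`healthy`), one status column per gene (`WT`/`mutant`), and
#'   `tm`.
#' @export
simulate_cohort <- function(n_patients,
                            prevalence = c(KRAS = 39 / 135, BRAF = 19 / 135,
                                           PI3K = 16 / 135),
                            tm_wt = 78.7, delta_tm_mut = 1.3,
                            noise_sd = 0.1, seed = NULL) {
  assert_scalar_number(n_patients, "n_patients", lower = 1)
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(names(prevalence)) || any(prevalence < 0 | prevalence > 1))
    stop("'prevalence' must be a named vector of fractions in [0, 1]")
  n <- as.integer(n_patients)
  with_seed(seed, {
    status <- sapply(names(prevalence), function(g) {
      k <- round(n * prevalence[[g]])
      s <- rep("WT", n)
      if (k > 0) s[sample.int(n, k)] <- "mutant"
      s
    })
    status <- matrix(status, nrow = n,
                     dimnames = list(NULL, names(prevalence)))
    any_mut <- apply(status == "mutant", 1, any)
    tm_tumor <- tm_wt - ifelse(any_mut, delta_tm_mut, 0) + rnorm(n, 0, noise_sd)
    tm_healthy <- tm_wt + rnorm(n, 0, noise_sd)
  })
  ids <- sprintf("P%03d", seq_len(n))
  tab <- data.frame(patient_id = rep(ids, each = 2L),
                    tissue = rep(c("tumor", "healthy"), times = n),
                    stringsAsFactors = FALSE)
  for (g in colnames(status)) tab[[g]] <- rep(status[, g], each = 2L)
  tab$tm <- as.vector(rbind(tm_tumor, tm_healthy))
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

genes_of <- function(table) {
  setdiff(colnames(table), c("patient_id", "tissue", "tm"))
}
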