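# Mutation-spectrum analysis of ungapped amplicon reads: 4x4 substitution
# matrices, per-site frequencies, hotspot-codon summaries, and
# base-composition / A+T-enrichment arithmetic.

# Normalize read input to a list(sequences, offsets). Accepts a read_set,
# a character vector of full-length products (offset 1), or a list with
# $sequences and $offsets.
as_read_input <- function(reads) {
  if (inherits(reads, "read_set"))
    return(list(sequences = reads$sequences, offsets = reads$offsets))
  if (is.character(reads))
    return(list(sequences = reads, offsets = rep(1L, length(reads))))
  if (is.list(reads) && !is.null(reads$sequences)) {
    off <- if (is.null(reads$offsets)) rep(1L, length(reads$sequences))
           else as.integer(reads$offsets)
    return(list(sequences = reads$sequences, offsets = off))
  }
  stop("'reads' must be a read_set, a character vector, or a list with $sequences")
}

# Long vectors of (reference position, ref base code, observed base code)
# across all compared bases; rejects reads running past the reference end.
compared_bases <- function(reads, ref) {
  rd <- as_read_input(reads)
  refint <- seq_to_int(as_bases(ref))
  L <- length(refint)
  lens <- nchar(rd$sequences)
  over <- which(rd$offsets < 1L | rd$offsets + lens - 1L > L)
  if (length(over))
    stop(sprintf("read %d (offset %d, length %d) extends outside the %d-nt reference",
                 over[1], rd$offsets[over[1]], lens[over[1]], L))
  obs <- unlist(lapply(rd$sequences, seq_to_int), use.names = FALSE)
  pos <- unlist(lapply(seq_along(lens),
                       function(i) rd$offsets[i] + seq_len(lens[i]) - 1L),
                use.names = FALSE)
  list(pos = pos, ref = refint[pos], obs = obs, ref_len = L)
}

#' Tally the 4x4 mutation matrix of a read set
#'
#' Every compared base increments exactly one cell of a 4x4
#' (reference base x observed base) count table; per-reference-base coverage
#' is the row total, so `frequency = counts / coverage`.
#'
#' @param reads A `read_set`, a character vector of full-length products, or
#'   a list with `$sequences` and `$offsets` (1-based).
#' @param ref Reference sequence.
#' @return Object of class `mutation_matrix`: list with `counts` (4x4
#'   integer), `coverage` (length-4), and `frequency` (4x4, `NA` rows where
#'   coverage is zero).
#' @export
tally_matrix <- function(reads, ref) {
  cb <- compared_bases(reads, ref)
  counts <- matrix(tabulate((cb$ref - 1L) * 4L + cb$obs, nbins = 16L),
                   4, 4, byrow = TRUE, dimnames = list(ref = BASES, obs = BASES))
  coverage <- rowSums(counts)
  freq <- counts / ifelse(coverage > 0, coverage, NA_real_)
  structure(list(counts = counts, coverage = coverage, frequency = freq),
            class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("<mutation_matrix> counts (ref x observed):\n")
  print(x$counts)
  cat(sprintf("overall frequency: %.4g\n", overall_frequency(x)))
  invisible(x)
}

#' Overall per-base mutation frequency of a mutation matrix
#'
#' Sum of off-diagonal counts over total coverage.
#'
#' @param matrix A [tally_matrix()] result.
#' @return Fraction in `[0, 1]`.
#' @export
overall_frequency <- function(matrix) {
  total <- sum(matrix$coverage)
  if (total <= 0) stop("zero total coverage")
  (total - sum(diag(matrix$counts))) / total
}

#' Per-site substitution frequencies
#'
#' @inheritParams tally_matrix
#' @param positions Optional subset of 1-based reference positions.
#' @return Data frame of class `site_frequency_table` with columns
#'   `position`, `ref`, `coverage`, `n_A`, `n_C`, `n_G`, `n_T`, `n_alt`, and
#'   `frequency` (`NA` where coverage is zero, never 0/0).
#' @export
site_frequency <- function(reads, ref, positions = NULL) {
  cb <- compared_bases(reads, ref)
  L <- cb$ref_len
  if (is.null(positions)) positions <- seq_len(L)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > L))
    stop("'positions' outside the reference")
  percell <- matrix(tabulate((cb$pos - 1L) * 4L + cb$obs, nbins = 4L * L),
                    L, 4, byrow = TRUE, dimnames = list(NULL, paste0("n_", BASES)))
  refint <- seq_to_int(as_bases(ref))
  cov <- rowSums(percell)
  nref <- percell[cbind(seq_len(L), refint)]
  out <- data.frame(position = seq_len(L), ref = BASES[refint],
                    coverage = cov, percell, n_alt = cov - nref,
                    frequency = ifelse(cov > 0, (cov - nref) / cov, NA_real_),
                    stringsAsFactors = FALSE)
  out <- out[out$position %in% positions, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_frequency_table", "data.frame")
  out
}

#' Hotspot-codon frequency report
#'
#' Summarizes per-site frequencies over the RAS hotspot codons 12 (nt
#' 34-36), 13 (nt 37-39) and 61 (nt 181-183); a codon's frequency is the
#' mean of its three per-site frequencies. Codons whose positions are not
#' covered by the table are dropped only if absent entirely; codons listed
#' in `codons` but missing positions are an error.
#'
#' @param table A [site_frequency()] result.
#' @param codons Codon indices to report; defaults to those of `table`'s
#'   span among 12, 13, 61.
#' @return Data frame with columns `codon`, `nt_start`, `nt_end`,
#'   `frequency`.
#' @export
hotspot_codon_report <- function(table, codons = NULL) {
  if (is.null(codons)) {
    codons <- HOTSPOT_CODONS[vapply(HOTSPOT_CODONS, function(k)
      all(codon_range(k) %in% table$position), logical(1))]
    if (!length(codons)) stop("table covers none of codons 12, 13, 61")
  }
  rows <- lapply(codons, function(k) {
    pos <- codon_range(k)
    if (!all(pos %in% table$position))
      stop(sprintf("positions %s required for codon %d are missing",
                   paste(setdiff(pos, table$position), collapse = ","), k))
    f <- table$frequency[match(pos, table$position)]
    data.frame(codon = k, nt_start = pos[1], nt_end = pos[3],
               frequency = mean(f))
  })
  do.call(rbind, rows)
}

#' Base composition of a sequence or of base counts
#'
#' @param source A sequence (string or `nucleotide_sequence`), a named
#'   A/C/G/T count vector, or a named percentage vector summing to 100.
#' @return Object of class `composition_summary`: named percentage vector
#'   over A, C, G, T with `at_percent` and `gc_percent` attributes.
#' @export
#' @examples
#' base_composition("ACGT") # 25% each
base_composition <- function(source) {
  if (is.numeric(source)) {
    counts <- source[BASES]
    if (anyNA(counts) || any(counts < 0))
      stop("numeric 'source' must be named non-negative A/C/G/T counts")
    total <- sum(counts)
    if (total <= 0) stop("empty composition")
    pct <- 100 * counts / total
  } else {
    idx <- seq_to_int(as_bases(source))
    pct <- 100 * tabulate(idx, 4) / length(idx)
    names(pct) <- BASES
  }
  structure(pct, at_percent = pct[["A"]] + pct[["T"]],
            gc_percent = pct[["C"]] + pct[["G"]],
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition_summary> A %.2f%% C %.2f%% G %.2f%% T %.2f%% (A+T %.2f%%)\n",
              x[["A"]], x[["C"]], x[["G"]], x[["T"]], attr(x, "at_percent")))
  invisible(x)
}

at_percent <- function(x) {
  if (inherits(x, "composition_summary")) attr(x, "at_percent")
  else attr(base_composition(x), "at_percent")
}

#' A+T enrichment between two compositions
#'
#' Fold change of the A+T percentage and its projection to an absolute
#' nucleotide gain over a genome:
#' `fold = AT_after / AT_before`;
#' `absolute_gain = (fold - 1) * (AT_before / 100) * genome_bp`.
#'
#' @param before,after [base_composition()] summaries (or inputs coercible
#'   by it).
#' @param genome_bp Genome size in base pairs for the absolute projection;
#'   default `6.2e9` (diploid human).
#' @return List with `fold` and `absolute_gain` (nucleotides).
#' @export
#' @examples
#' pair <- simulate_composition_pair(c(A = 30, C = 21, G = 20, T = 29), 1.03)
#' at_enrichment(pair$before, pair$after)$fold # 1.03
at_enrichment <- function(before, after, genome_bp = 6.2e9) {
  assert_scalar_number(genome_bp, "genome_bp", lower = 1)
  at0 <- at_percent(before); at1 <- at_percent(after)
  if (at0 <= 0) stop("baseline A+T percentage is zero")
  fold <- at1 / at0
  list(fold = fold, absolute_gain = (fold - 1) * (at0 / 100) * genome_bp)
}
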