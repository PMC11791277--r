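# Low-level nucleotide utilities shared by all modules.
#
# Sequences are plain upper-case ACGT character strings with 1-based,
# inclusive coordinates; codon k spans nucleotides 3k-2..3k. Internally most
# routines work on integer vectors over 1..4 (A,C,G,T) for speed.

BASES <- c("A", "C", "G", "T")
# Watson-Crick partner indices: A<->T, C<->G
COMP_IDX <- c(4L, 3L, 2L, 1L)

# RAS hotspot codons and the CDS nucleotide ranges they span.
HOTSPOT_CODONS <- c(12L, 13L, 61L)

#' Nucleotide range of a codon
#'
#' Codon `k` of a coding sequence spans nucleotides `3k - 2` to `3k`
#' (1-based, inclusive), so codon 12 covers nt 34-36 and codon 61 nt 181-183.
#'
#' @param codon Integer codon index (1-based).
#' @return Integer vector of the three CDS positions.
#' @export
#' @examples
#' codon_range(12) # 34 35 36
codon_range <- function(codon) {
  codon <- as.integer(codon)
  stopifnot(all(codon >= 1L))
  as.integer(vapply(codon, function(k) (3L * k - 2L):(3L * k), integer(3)))
}

# Convert an ACGT string to integer codes 1..4, rejecting ambiguity codes.
seq_to_int <- function(x) {
  if (length(x) != 1L || !is.character(x) || is.na(x) || nchar(x) == 0L)
    stop("sequence must be a single non-empty character string")
  idx <- match(charToRaw(toupper(x)), charToRaw("ACGT"))
  if (anyNA(idx)) {
    bad <- substr(toupper(x), which(is.na(idx))[1], which(is.na(idx))[1])
    stop(sprintf("sequence contains non-ACGT character '%s'", bad))
  }
  idx
}

int_to_seq <- function(idx) {
  rawToChar(charToRaw("ACGT")[idx])
}

comp_int <- function(idx) COMP_IDX[idx]

# Run an expression with the RNG seeded, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper))
  invisible(x)
}
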