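# Codon-level annotation of coding variants, RAS hotspot and
# transforming-residue rules, and free-energy-change (ddG) stability
# classification.

#' A single-nucleotide coding variant
#'
#' @param position 1-based CDS nucleotide index.
#' @param ref,alt Reference and alternative base (`A`/`C`/`G`/`T`, unequal).
#' @return Object of class `coding_variant`.
#' @export
coding_variant <- function(position, ref, alt) {
  assert_scalar_number(position, "position", lower = 1)
  if (!(ref %in% BASES) || !(alt %in% BASES)) stop("ref and alt must be A/C/G/T")
  if (ref == alt) stop("ref and alt must differ")
  structure(list(position = as.integer(position), ref = ref, alt = alt),
            class = "coding_variant")
}

#' Annotate a coding variant at the codon level
#'
#' Translates the affected codon with the standard genetic code and flags
#' hotspot codons (12, 13, 61), synonymous changes, and CG>TA-class
#' transitions (C>T or G>A).
#'
#' @param variant A [coding_variant()] (or a list with `position`, `ref`,
#'   `alt`).
#' @param cds Coding sequence; length must be a multiple of 3 and the
#'   reference base must match the CDS at the variant position (guards
#'   coordinate bugs).
#' @return Object of class `consequence`: list with `position`, `ref_base`,
#'   `alt_base`, `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`
#'   (single-letter), `synonymous`, `hotspot`, `cg_to_ta`.
#' @export
#' @examples
#' cds <- make_reference(reference_spec(183, hotspot_template = TRUE, seed = 7))
#' annotate(coding_variant(34, "G", "T"), cds) # Gly12Cys, hotspot
annotate <- function(variant, cds) {
  if (!inherits(variant, "coding_variant"))
    variant <- coding_variant(variant$position, variant$ref, variant$alt)
  bases <- as_bases(cds)
  L <- nchar(bases)
  if (L %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (variant$position > L) stop("variant position beyond CDS end")
  if (substr(bases, variant$position, variant$position) != variant$ref)
    stop(sprintf("reference mismatch: CDS has '%s' at position %d, variant says '%s'",
                 substr(bases, variant$position, variant$position),
                 variant$position, variant$ref))
  k <- ceiling(variant$position / 3)
  pos <- codon_range(k)
  ref_codon <- substr(bases, pos[1], pos[3])
  alt_codon <- ref_codon
  substr(alt_codon, variant$position - pos[1] + 1L,
         variant$position - pos[1] + 1L) <- variant$alt
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon]); alt_aa <- unname(code[alt_codon])
  structure(list(position = variant$position, ref_base = variant$ref,
                 alt_base = variant$alt, codon_index = k,
                 ref_codon = ref_codon, alt_codon = alt_codon,
                 ref_aa = ref_aa, alt_aa = alt_aa,
                 synonymous = identical(ref_aa, alt_aa),
                 hotspot = k %in% HOTSPOT_CODONS,
                 cg_to_ta = (variant$ref == "C" && variant$alt == "T") ||
                            (variant$ref == "G" && variant$alt == "A")),
            class = "consequence")
}

#' @export
print.consequence <- function(x, ...) {
  cat(sprintf("<consequence> %s%d%s | codon %d %s>%s (%s>%s)%s%s%s\n",
              x$ref_base, x$position, x$alt_base, x$codon_index,
              x$ref_codon, x$alt_codon, x$ref_aa, x$alt_aa,
              if (x$synonymous) " synonymous" else "",
              if (x$hotspot) " hotspot" else "",
              if (x$cg_to_ta) " CG>TA" else ""))
  invisible(x)
}

#' Transforming-residue rule for codon 12
#'
#' Glycine 12 substitutions to any residue except glycine (synonymous) or
#' proline are transforming in the focus-formation sense; substitutions at
#' other codons - including hotspots 13 and 61 - return `FALSE` under this
#' rule (they are surfaced by the hotspot flag instead).
#'
#' @param consequence An [annotate()] result.
#' @return Logical.
#' @export
is_transforming <- function(consequence) {
  stopifnot(inherits(consequence, "consequence"))
  consequence$codon_index == 12L &&
    !(consequence$alt_aa %in% c("G", "P"))
}

#' Classify protein stability changes from ddG values
#'
#' A mutation is stabilizing if ddG < -3 kcal/mol, destabilizing if
#' ddG > 3 kcal/mol, and neutral otherwise; the boundaries +/-3 are neutral
#' (strict inequalities).
#'
#' @param ddg Numeric vector of free-energy changes (kcal/mol), finite.
#' @return Character vector over `"stabilizing"`, `"neutral"`,
#'   `"destabilizing"`.
#' @export
#' @examples
#' classify_stability(c(-0.49, 3.2, 21)) # neutral, destabilizing, destabilizing
classify_stability <- function(ddg) {
  if (!is.numeric(ddg) || any(!is.finite(ddg)))
    stop("ddG values must be finite numbers")
  ifelse(ddg < -3, "stabilizing", ifelse(ddg > 3, "destabilizing", "neutral"))
}

#' Count stability records per class
#'
#' @param records Numeric ddG vector, or a data frame with a `ddg` column
#'   (e.g. read from a two-column label/ddG TSV).
#' @return Named integer vector with entries `stabilizing`, `neutral`,
#'   `destabilizing` (all classes always present; counts sum to the input
#'   length).
#' @export
count_by_class <- function(records) {
  ddg <- if (is.data.frame(records)) records$ddg else records
  if (!length(ddg)) stop("no stability records supplied")
  cls <- factor(classify_stability(ddg),
                levels = c("stabilizing", "neutral", "destabilizing"))
  c(table(cls))
}

#' Apply a variant to a CDS
#'
#' Utility for round-trip checks: returns the CDS with the variant's
#' alternative base substituted.
#'
#' @param variant A [coding_variant()].
#' @param cds Coding sequence.
#' @return Character string of the mutated CDS.
#' @export
apply_variant <- function(variant, cds) {
  bases <- as_bases(cds)
  if (substr(bases, variant$position, variant$position) != variant$ref)
    stop("reference mismatch")
  substr(bases, variant$position, variant$position) <- variant$alt
  bases
}
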