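# Error-prone PCR under unequal dNTP pools.
#
# Misincorporation competes with correct Watson-Crick incorporation: for a
# template base b the correct dNTP enters with weight [correct dNTP] and a
# wrong base x with weight delta(b, x) * [dNTP_x], where delta is the
# polymerase discrimination factor. With [dTTP] >> [dCTP] the dG:dT mispair
# dominates; because mispairs arise while copying either strand of the
# amplicon, they surface as both C>T and G>A on the reported strand.

#' dNTP pool concentrations
#'
#' @param dATP,dCTP,dGTP,dTTP Concentrations in micromolar; all strictly
#'   positive.
#' @return An object of class `dntp_pool`.
#' @export
#' @examples
#' mut_pool <- dntp_pool(dATP = 50, dCTP = 10, dGTP = 50, dTTP = 1000)
#' dntp_ratio(mut_pool) # [dTTP]/[dCTP] = 100
dntp_pool <- function(dATP = 50, dCTP = 50, dGTP = 50, dTTP = 50) {
  conc <- c(A = dATP, C = dCTP, G = dGTP, T = dTTP)
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all four dNTP concentrations must be strictly positive")
  structure(list(conc = conc), class = "dntp_pool")
}

#' @export
print.dntp_pool <- function(x, ...) {
  cat("<dntp_pool> (uM):",
      paste(sprintf("d%sTP=%g", names(x$conc), x$conc), collapse = " "),
      sprintf(" [dTTP]/[dCTP]=%g\n", dntp_ratio(x)))
  invisible(x)
}

#' The mutagenic [dTTP]/[dCTP] ratio of a pool
#' @param pool A [dntp_pool()].
#' @return Numeric ratio.
#' @export
dntp_ratio <- function(pool) pool$conc[["T"]] / pool$conc[["C"]]

#' The biased-dCTP pool series used for mutagenic PCR
#'
#' dTTP at 1000 uM, dATP and dGTP at 50 uM, with dCTP swept over the given
#' levels (default 1000, 100, 50, 30, 10 uM, i.e. ratios 1 to 100).
#'
#' @param dctp Numeric vector of dCTP concentrations (uM).
#' @return Named list of [dntp_pool()] objects, one per dCTP level.
#' @export
mutpcr_pool_series <- function(dctp = c(1000, 100, 50, 30, 10)) {
  stats::setNames(lapply(dctp, function(c) dntp_pool(50, c, 50, 1000)),
                  sprintf("dCTP_%g", dctp))
}

#' Polymerase misincorporation model
#'
#' `delta` maps (template base, wrong incorporated base) to a non-negative
#' discrimination factor; the Watson-Crick partner always incorporates with
#' factor 1. Defaults encode the transition-producing dG:dT mispair and its
#' antisense image (delta(G,T) = delta(C,A) = 1e-4), zero elsewhere.
#'
#' @param delta Named numeric vector, names like `"G>T"` meaning template G
#'   misincorporating dTTP.
#' @param default_delta Factor for unspecified pairs.
#' @return An object of class `misincorporation_model` holding a 4x4 delta
#'   matrix (rows = template base, columns = incorporated base; the
#'   Watson-Crick cell is `NA`).
#' @export
misincorporation_model <- function(delta = c("G>T" = 1e-4, "C>A" = 1e-4),
                                   default_delta = 0) {
  assert_scalar_number(default_delta, "default_delta", lower = 0)
  m <- matrix(default_delta, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) m[i, BASES[COMP_IDX[i]]] <- NA_real_
  if (length(delta)) {
    if (is.null(names(delta))) stop("'delta' must be named like 'G>T'")
    parts <- strsplit(names(delta), ">", fixed = TRUE)
    for (j in seq_along(delta)) {
      tb <- parts[[j]][1]; wb <- parts[[j]][2]
      if (!(tb %in% BASES) || !(wb %in% BASES))
        stop(sprintf("bad delta name '%s'", names(delta)[j]))
      if (wb == BASES[COMP_IDX[match(tb, BASES)]])
        stop(sprintf("'%s' is the Watson-Crick pairing, not a mispair",
                     names(delta)[j]))
      if (!is.finite(delta[[j]]) || delta[[j]] < 0)
        stop("delta factors must be finite and >= 0")
      m[tb, wb] <- delta[[j]]
    }
  }
  structure(list(delta = m), class = "misincorporation_model")
}

#' Incorporation probabilities opposite a template base
#'
#' The probability of incorporating base x opposite template base b is
#' `w(x) / sum(w)` with `w(correct) = [correct dNTP]` and
#' `w(wrong x) = delta(b, x) * [dNTP_x]`.
#'
#' @param template_base One of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param pool A [dntp_pool()].
#' @param model A [misincorporation_model()].
#' @return Named probability vector over the four incorporable bases
#'   (sums to 1).
#' @export
incorporation_probs <- function(template_base, pool, model) {
  b <- match(template_base, BASES)
  if (is.na(b)) stop("template_base must be one of A, C, G, T")
  incorporation_matrix(pool, model)[b, ]
}

# 4x4 matrix of incorporation probabilities, rows = template base.
incorporation_matrix <- function(pool, model) {
  w <- model$delta * rep(pool$conc, each = 4)
  for (i in 1:4) w[i, COMP_IDX[i]] <- pool$conc[[COMP_IDX[i]]]
  w / rowSums(w)
}

# Draw the complementary copy of an integer-coded template given row-wise
# cumulative incorporation probabilities. Returned in the same reference
# coordinates (entry i pairs with template position i).
replicate_int <- function(tint, cum) {
  u <- runif(length(tint))
  1L + (u > cum[tint, 1L]) + (u > cum[tint, 2L]) + (u > cum[tint, 3L])
}

#' Copy a template strand once through the polymerase model
#'
#' Each output base is drawn independently from [incorporation_probs()] of
#' its template base. The copy is returned 5'->3' (i.e. the reverse of the
#' incorporation order along the template), with misincorporated template
#' positions recorded.
#'
#' @param template Template sequence (string or `nucleotide_sequence`).
#' @param pool A [dntp_pool()].
#' @param model A [misincorporation_model()].
#' @param seed Optional seed for a reproducible single copy.
#' @return List with `copy` (character, 5'->3' on the nascent strand) and
#'   `mis_positions` (1-based template positions where the incorporated base
#'   was not the Watson-Crick partner).
#' @export
replication_step <- function(template, pool, model, seed = NULL) {
  tint <- seq_to_int(as_bases(template))
  cum <- t(apply(incorporation_matrix(pool, model), 1, cumsum))
  inc <- with_seed(seed, replicate_int(tint, cum))
  mis <- which(inc != comp_int(tint))
  list(copy = int_to_seq(rev(inc)), mis_positions = mis)
}

#' PCR run parameters
#'
#' @param cycles Number of thermal cycles (default 50).
#' @param dup_prob Per-cycle probability that a lineage is copied (0, 1].
#' @param n_products Number of final molecules to sample.
#' @param seed Integer seed.
#' @return Object of class `pcr_run`.
#' @export
pcr_run <- function(cycles = 50, dup_prob = 0.9, n_products = 1000,
                    seed = NULL) {
  assert_scalar_number(cycles, "cycles", lower = 1)
  assert_scalar_number(dup_prob, "dup_prob", lower = 1e-12, upper = 1)
  assert_scalar_number(n_products, "n_products", lower = 1)
  structure(list(cycles = as.integer(cycles), dup_prob = dup_prob,
                 n_products = as.integer(n_products), seed = seed),
            class = "pcr_run")
}

#' Simulate error-prone PCR by lineage sampling
#'
#' Each final molecule is generated by an independent lineage walk starting
#' from either strand of the double-stranded template with equal
#' probability: at every cycle a copy event occurs with probability
#' `dup_prob`; each copy applies the misincorporation model to the current
#' strand and flips the tracked strand, so dG:dT mispairs arising on either
#' strand surface as both C>T and G>A on the reported strand (in balanced
#' proportions, since sense- and antisense-started lineages see the two
#' strand phases equally often). Lineages ending on the antisense strand
#' are complemented back to template orientation.
#'
#' @param template Template sequence (string or `nucleotide_sequence`).
#' @param pool A [dntp_pool()].
#' @param model A [misincorporation_model()].
#' @param run A [pcr_run()].
#' @return Character vector of product sequences, all in template
#'   orientation and template coordinates.
#' @export
simulate_pcr <- function(template, pool, model, run = pcr_run()) {
  tint0 <- seq_to_int(as_bases(template))
  cum <- t(apply(incorporation_matrix(pool, model), 1, cumsum))
  with_seed(run$seed, {
    vapply(seq_len(run$n_products), function(i) {
      antisense <- runif(1) < 0.5 # dsDNA template: either strand seeds the lineage
      b <- if (antisense) comp_int(tint0) else tint0
      copies <- sum(runif(run$cycles) < run$dup_prob)
      for (k in seq_len(copies)) {
        b <- replicate_int(b, cum)
        antisense <- !antisense
      }
      if (antisense) b <- comp_int(b)
      int_to_seq(b)
    }, character(1))
  })
}

#' Per-base mutation frequency of PCR products
#'
#' Total mismatched bases over total compared bases, all products against
#' the reference.
#'
#' @param products Character vector of product sequences (template
#'   orientation, full length).
#' @param reference Reference sequence.
#' @return Fraction in `[0, 1]`.
#' @export
mutation_frequency <- function(products, reference) {
  refint <- seq_to_int(as_bases(reference))
  if (!length(products)) stop("no products supplied")
  mism <- vapply(products, function(p) {
    pint <- seq_to_int(p)
    if (length(pint) != length(refint))
      stop("product length differs from reference length")
    sum(pint != refint)
  }, numeric(1), USE.NAMES = FALSE)
  sum(mism) / (length(products) * length(refint))
}
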