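# Cohort-level screening: mutation prevalence, paired tumor-vs-healthy Tm
# permutation tests, and delta-delta-Ct fold-change arithmetic for qPCR.

# Half-up integer rounding for display percentages (R's round() is
# half-to-even; prevalence displays follow the half-up convention).
round_half_up <- function(x) floor(x + 0.5)

#' Mutation prevalence of a gene in a cohort
#'
#' Counts mutant patients (one tumor/healthy pair each) for a gene.
#'
#' @param table A `cohort_table` (see [simulate_cohort()]), or any data
#'   frame with `patient_id` and a per-gene status column.
#' @param gene Gene name (a status column of `table`).
#' @return List of class `prevalence_report`: `gene`, `n_mutant`, `n_total`,
#'   `fraction` (exact) and `percent_display` (half-up integer).
#' @export
#' @examples
#' cohort <- simulate_cohort(135, seed = 1)
#' prevalence(cohort, "KRAS") # 39/135, ~29%
prevalence <- function(table, gene) {
  if (!(gene %in% genes_of(table)))
    stop(sprintf("gene '%s' not present in the cohort table", gene))
  per_patient <- table[!duplicated(table$patient_id), , drop = FALSE]
  n_total <- nrow(per_patient)
  n_mutant <- sum(per_patient[[gene]] == "mutant")
  fraction <- n_mutant / n_total
  structure(list(gene = gene, n_mutant = n_mutant, n_total = n_total,
                 fraction = fraction,
                 percent_display = round_half_up(100 * fraction)),
            class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat(sprintf("<prevalence_report> %s: %d/%d (%.1f%%, displayed ~%d%%)\n",
              x$gene, x$n_mutant, x$n_total, 100 * x$fraction,
              x$percent_display))
  invisible(x)
}

# Paired tumor - healthy Tm differences for the selected patients.
paired_tm_diffs <- function(table, gene = NULL, status = "mutant") {
  tab <- as.data.frame(table)
  if (!is.null(gene)) {
    if (!(gene %in% genes_of(tab))) stop(sprintf("gene '%s' not in table", gene))
    keep <- tab$patient_id[tab[[gene]] == status & tab$tissue == "tumor"]
    tab <- tab[tab$patient_id %in% keep, , drop = FALSE]
  }
  tumor <- tab[tab$tissue == "tumor", c("patient_id", "tm")]
  healthy <- tab[tab$tissue == "healthy", c("patient_id", "tm")]
  unpaired <- c(setdiff(tumor$patient_id, healthy$patient_id),
                setdiff(healthy$patient_id, tumor$patient_id))
  if (length(unpaired))
    stop("unpaired patients: ", paste(unique(unpaired), collapse = ", "))
  if (anyDuplicated(tumor$patient_id) || anyDuplicated(healthy$patient_id))
    stop("patients with duplicated tissue rows: ",
         paste(unique(c(tumor$patient_id[duplicated(tumor$patient_id)],
                        healthy$patient_id[duplicated(healthy$patient_id)])),
               collapse = ", "))
  tumor$tm[match(healthy$patient_id, tumor$patient_id)] - healthy$tm
}

#' Paired tumor-vs-healthy Tm shift test
#'
#' Statistic: mean paired difference `tumor Tm - healthy Tm` over the
#' selected patients. Significance by a one-sided sign-flip permutation
#' test (probability of a permuted statistic at or below the observed one;
#' mutant alleles melt lower), with the add-one convention
#' `p = (1 + #{perm <= obs}) / (n_perm + 1)` so p is never zero.
#'
#' @param table Cohort table with paired tumor/healthy rows per patient.
#' @param gene Optional gene: restrict to patients whose status for that
#'   gene equals `status`.
#' @param status Gene status filter (default `"mutant"`).
#' @param n_perm Number of sign-flip permutations (default 9999).
#' @param seed Integer seed; the test is deterministic given it.
#' @return List with `statistic` (mean paired delta-Tm, degC), `p_value`,
#'   `n_patients`, `n_perm`.
#' @export
tm_shift_test <- function(table, gene = NULL, status = "mutant",
                          n_perm = 9999, seed = NULL) {
  if (n_perm < 999) stop("n_perm must be at least 999")
  d <- paired_tm_diffs(table, gene, status)
  n <- length(d)
  if (n == 0) stop("no patients match the requested gene status")
  obs <- mean(d)
  perm <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    colMeans(signs * d)
  })
  p <- (1 + sum(perm <= obs)) / (n_perm + 1)
  list(statistic = obs, p_value = p, n_patients = n, n_perm = n_perm)
}

#' A qPCR measurement (target and reference Ct)
#'
#' @param ct_target Cycle threshold of the target gene (e.g. mitochondrial
#'   MT-COI in the cytosolic fraction).
#' @param ct_reference Cycle threshold of the normalizing nuclear gene
#'   (e.g. B2M in the whole-cell fraction).
#' @return Object of class `qpcr_measurement`.
#' @export
qpcr_measurement <- function(ct_target, ct_reference) {
  assert_scalar_number(ct_target, "ct_target")
  assert_scalar_number(ct_reference, "ct_reference")
  structure(list(ct_target = ct_target, ct_reference = ct_reference),
            class = "qpcr_measurement")
}

#' Delta-delta-Ct fold change
#'
#' `dCt = ct_target - ct_reference` per specimen;
#' `ddCt = dCt_sample - dCt_calibrator`; fold change `2^(-ddCt)`.
#'
#' @param sample,calibrator [qpcr_measurement()] objects.
#' @return Numeric fold change.
#' @export
#' @examples
#' ddct_fold(qpcr_measurement(24, 20), qpcr_measurement(25, 20)) # 2
ddct_fold <- function(sample, calibrator) {
  stopifnot(inherits(sample, "qpcr_measurement"),
            inherits(calibrator, "qpcr_measurement"))
  dct_s <- sample$ct_target - sample$ct_reference
  dct_c <- calibrator$ct_target - calibrator$ct_reference
  2^(-(dct_s - dct_c))
}
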