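test_that("hydrogen bond counting: 3 per G:C, 2 per A:T, additive", {
  expect_equal(hydrogen_bond_count("GC"), 6)
  expect_equal(hydrogen_bond_count("AT"), 4)
  expect_error(hydrogen_bond_count("ACGN"), "non-ACGT")
  set.seed(31)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = "")
    y <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    expect_equal(hydrogen_bond_count(paste0(x, y)),
                 hydrogen_bond_count(x) + hydrogen_bond_count(y))
  }
  # one C>T transition in a 30-nt window loses exactly one bond
  win <- make_reference(reference_spec(30, gc_target = 0.5, seed = 1))$bases
  cpos <- regexpr("C", win)
  mut <- win; substr(mut, cpos, cpos) <- "T"
  expect_equal(hydrogen_bond_count(win) - hydrogen_bond_count(mut), 1)
})

test_that("GC percentage and generator tolerance", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATGC"), 50)
  kras_like <- make_reference(reference_spec(500, gc_target = 0.376, seed = 2))
  expect_lt(abs(gc_percent(kras_like$bases) - 37.6), 2)
})

test_that("Tm formula evaluates exactly and couples to CG>TA transitions", {
  # 30-mer, 50% GC, 50 mM Na+: 81.5 + 16.6 log10(0.05) + 20.5 - 22.5
  win <- strrep("ACGT", 7) # 28-mer, pad to 30 below
  win30 <- paste0(win, "AC") # GC 50% over 30 nt
  expect_equal(gc_percent(win30), 50)
  expect_equal(tm_estimate(win30),
               81.5 + 16.6 * log10(0.05) + 0.41 * 50 - 675 / 30,
               tolerance = 1e-12) # ~57.91 degC
  expect_error(tm_estimate("ACGTACGTACGT"), "length >= 14")

  # exact coupling: k transitions shift Tm by -0.41 * 100/L * k
  set.seed(33)
  for (k in c(1, 3, 7)) {
    L <- 50
    seq0 <- paste(sample(c("G", "C"), L, replace = TRUE), collapse = "")
    mut <- strsplit(seq0, "")[[1]]
    idx <- sample(L, k)
    mut[idx] <- ifelse(mut[idx] == "C", "T", "A")
    expect_equal(tm_estimate(paste(mut, collapse = "")) - tm_estimate(seq0),
                 -0.41 * (100 / L) * k, tolerance = 1e-9)
  }
  # HRAS-like vs KRAS-like GC content: higher GC melts higher
  expect_equal(0.41 * (59.1 - 37.6), 8.815)
  hi <- make_reference(reference_spec(200, gc_target = 0.591, seed = 3))
  lo <- make_reference(reference_spec(200, gc_target = 0.376, seed = 3))
  expect_gt(tm_estimate(hi$bases), tm_estimate(lo$bases))
})

test_that("melting curves recover peaks and resolve mixtures", {
  for (w in c(0.1, 0.3, 1)) {
    prof <- melt_curve(data.frame(weight = 1, tm = 78.7),
                       thermo_params(sigmoid_width = w))
    expect_lte(abs(prof$tm_called - 78.7), 0.1) # within one grid step
    expect_true(all(diff(prof$fluorescence) <= 0))
  }
  # two species 77.4 / 78.7 degC at width 0.3: bimodal derivative
  mix <- melt_curve(data.frame(weight = c(0.5, 0.5), tm = c(77.4, 78.7)),
                    thermo_params(sigmoid_width = 0.3))
  d <- mix$derivative
  local_max <- which(diff(sign(diff(d))) == -2) + 1
  peaks <- mix$temps[local_max][d[local_max] > 0.1 * max(d)]
  expect_gte(length(peaks), 2)
  expect_lt(min(abs(peaks - 77.4)), 0.2)
  expect_lt(min(abs(peaks - 78.7)), 0.2)
  # a zero-weight species contributes nothing
  one <- melt_curve(data.frame(weight = 1, tm = 80))
  two <- melt_curve(data.frame(weight = c(1, 0), tm = c(80, 85)),
                    temps = one$temps)
  expect_equal(two$fluorescence, one$fluorescence)
  expect_error(melt_curve(data.frame(weight = numeric(0), tm = numeric(0))),
               "empty")
})

test_that("Tm-shift genotyping follows the threshold rule", {
  params <- thermo_params(delta_tm_threshold = 0.4)
  expect_equal(classify_sample(78.7, wt_tm = 78.7, params), "WT")
  expect_equal(classify_sample(77.4, wt_tm = 78.7, params), "mutant")
  strict <- thermo_params(delta_tm_threshold = 0)
  expect_equal(classify_sample(78.69, wt_tm = 78.7, strict), "mutant")
  # threshold above the injected shift flips the call back to WT
  wide <- thermo_params(delta_tm_threshold = 2)
  expect_equal(classify_sample(77.4, wt_tm = 78.7, wide), "WT")
  # via a full profile
  prof <- melt_curve(data.frame(weight = 1, tm = 77.4))
  expect_equal(classify_sample(prof, wt_tm = 78.7, params), "mutant")
})

test_that("denaturation-gradient selection is nested and formula-exact", {
  set.seed(37)
  seqs <- stats::setNames(lapply(1:8, function(i)
    make_reference(reference_spec(150, gc_target = runif(1, 0.3, 0.7),
                                  seed = i))$bases), paste0("s", 1:8))
  sel <- td_selection(seqs, gradient = seq(50, 90, by = 1))
  for (i in seq_along(sel$recovered)[-1])
    expect_true(all(sel$recovered[[i - 1]] %in% sel$recovered[[i]]))
  # single sequence: recovered at all T >= Td, absent below
  td <- sel$td[["s1"]]
  one <- td_selection(seqs["s1"], gradient = c(td - 0.5, td, td + 0.5))
  expect_equal(lengths(one$recovered), c(0L, 1L, 1L), ignore_attr = TRUE)
  # ten CG>TA transitions in a 200-mer lower Td by exactly 2.05 degC
  base <- make_reference(reference_spec(200, gc_target = 0.6, seed = 9))$bases
  mut <- strsplit(base, "")[[1]]
  idx <- which(mut %in% c("C", "G"))[1:10]
  mut[idx] <- ifelse(mut[idx] == "C", "T", "A")
  pair <- td_selection(c(wt = base, mut = paste(mut, collapse = "")),
                       gradient = 80)
  expect_equal(pair$td[["wt"]] - pair$td[["mut"]],
               0.41 * (10 / 200) * 100, tolerance = 1e-9)
})

test_that("a CG>TA-loaded population is recovered at lower temperatures", {
  ref <- hotspot_ref(length = 200)
  high <- simulate_pcr(ref, dntp_pool(50, 10, 50, 1000),
                       misincorporation_model(),
                       pcr_run(cycles = 30, n_products = 50, seed = 41))
  low <- simulate_pcr(ref, dntp_pool(50, 1000, 50, 1000),
                      misincorporation_model(),
                      pcr_run(cycles = 30, n_products = 50, seed = 42))
  sel <- td_selection(c(stats::setNames(high, paste0("hi", 1:50)),
                        stats::setNames(low, paste0("lo", 1:50))),
                      gradient = seq(70, 85, by = 0.25))
  min_t <- function(prefix) {
    hit <- vapply(sel$recovered, function(ids) any(startsWith(ids, prefix)),
                  logical(1))
    sel$gradient[which(hit)[1]]
  }
  expect_lt(min_t("hi"), min_t("lo"))
})
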