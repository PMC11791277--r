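test_that("mutation matrix matches a hand tally and conserves counts", {
  ref <- list(id = "toy", bases = "ACGT")
  class(ref) <- "nucleotide_sequence"
  m <- tally_matrix(c("ACGT", "ATGT"), ref)
  expect_equal(m$counts["C", "T"], 1)
  expect_equal(m$coverage[["C"]], 2)
  expect_equal(m$frequency["C", "T"], 0.5)
  expect_equal(sum(m$counts), 8) # every compared base lands in one cell
  expect_equal(overall_frequency(m), 1 / 8)

  clean <- tally_matrix(c("ACGT", "ACGT"), ref)
  expect_true(all(clean$counts[row(clean$counts) != col(clean$counts)] == 0))
  expect_equal(overall_frequency(clean), 0)
})

test_that("reads extending past the reference are rejected with a position", {
  ref <- hotspot_ref()
  expect_error(
    tally_matrix(list(sequences = strrep("A", 100), offsets = 150L), ref),
    "extends outside")
  expect_error(site_frequency(c("ACGT"), ref, positions = 500), "outside")
})

test_that("tally equals the brute-force double-loop oracle", {
  ref <- hotspot_ref()
  rs <- simulate_reads(ref, rate = 0.02, n_reads = 300, read_len = 70,
                       seed = 13)
  m <- tally_matrix(rs, ref)
  expect_identical(unname(m$counts),
                   unname(oracle_tally(rs$sequences, rs$offsets, ref$bases)))
  expect_equal(sum(m$counts), 300 * 70)
})

test_that("site frequencies recover a single-position injected rate", {
  ref <- hotspot_ref()
  rates <- rep(0, 183); rates[34] <- 0.02
  rs <- simulate_reads(ref, rate = rates, n_reads = 20000, read_len = 150,
                       seed = 17)
  sf <- site_frequency(rs, ref)
  cov34 <- sf$coverage[sf$position == 34]
  se <- sqrt(0.02 * 0.98 / cov34)
  expect_lt(abs(sf$frequency[sf$position == 34] - 0.02), 3 * se)
  expect_equal(sf$frequency[sf$position == 35], 0)
  # subsetting preserves values
  sub <- site_frequency(rs, ref, positions = 30:40)
  expect_equal(sub$frequency, sf$frequency[sf$position %in% 30:40])
})

test_that("zero-coverage positions are flagged as missing, never zero", {
  ref <- hotspot_ref()
  rs <- list(sequences = substr(ref$bases, 1, 50), offsets = 1L)
  sf <- site_frequency(rs, ref)
  expect_true(all(is.na(sf$frequency[sf$position > 50])))
  expect_true(all(sf$frequency[sf$position <= 50] == 0))
})

test_that("subset frequency equals the coverage-weighted mean of site rates", {
  ref <- hotspot_ref()
  rs <- simulate_reads(ref, rate = 0.01, n_reads = 500, read_len = 90,
                       seed = 19)
  sf <- site_frequency(rs, ref)
  sub <- sf[sf$position %in% 20:60, ]
  weighted <- sum(sub$n_alt) / sum(sub$coverage)
  expect_equal(weighted,
               sum(sub$frequency * sub$coverage) / sum(sub$coverage))
})

test_that("hotspot codon report averages the three per-site frequencies", {
  tab <- data.frame(position = 34:39,
                    frequency = c(0.01, 0.02, 0.03, 0, 0, 0))
  rep12 <- hotspot_codon_report(tab, codons = 12)
  expect_equal(rep12$frequency, 0.02)
  expect_equal(rep12$nt_start, 34); expect_equal(rep12$nt_end, 36)
  expect_error(hotspot_codon_report(tab, codons = 61), "missing")
  both <- hotspot_codon_report(tab)
  expect_equal(both$codon, c(12, 13)) # codon 61 absent from a 178-bp-style span
  zero <- hotspot_codon_report(data.frame(position = 34:39, frequency = 0))
  expect_true(all(zero$frequency == 0))
})

test_that("biased-pool PCR products show CG>TA dominance at hotspot G/C sites", {
  ref <- hotspot_ref()
  prods <- simulate_pcr(ref, dntp_pool(50, 10, 50, 1000),
                        misincorporation_model(),
                        pcr_run(cycles = 30, n_products = 400, seed = 23))
  m <- tally_matrix(prods, ref)
  off <- m$frequency; off[row(off) == col(off)] <- NA
  top2 <- sort(off[!is.na(off)], decreasing = TRUE)[1:2]
  expect_setequal(round(c(m$frequency["C", "T"], m$frequency["G", "A"]), 12),
                  round(top2, 12))
  sf <- site_frequency(prods, ref)
  gc_sites <- c(34, 35, 36, 37, 38, 181, 183) # G/C of codons 12/13/61
  at_sites <- c(39, 182)                      # T39, A182
  expect_gt(min(sf$frequency[sf$position %in% gc_sites]),
            max(sf$frequency[sf$position %in% at_sites]))
})

test_that("base composition percentages behave and validate", {
  expect_equal(attr(base_composition("ATAT"), "at_percent"), 100)
  expect_equal(as.numeric(base_composition("ACGT")), rep(25, 4))
  cc <- base_composition(c(A = 30, T = 29, C = 21, G = 20))
  expect_equal(attr(cc, "at_percent"), 59)
  expect_equal(sum(cc), 100, tolerance = 1e-9)
  expect_error(base_composition(c(A = 0, C = 0, G = 0, T = 0)), "empty")
})

test_that("A+T enrichment arithmetic matches closed forms", {
  same <- base_composition(c(A = 25, C = 25, G = 25, T = 25))
  expect_equal(at_enrichment(same, same)$fold, 1)
  expect_equal(at_enrichment(same, same)$absolute_gain, 0)
  # 59% baseline, 1.03-fold, diploid human genome
  pair <- simulate_composition_pair(c(A = 30, C = 20.5, G = 20.5, T = 29), 1.03)
  gain <- at_enrichment(pair$before, pair$after, genome_bp = 6.2e9)$absolute_gain
  expect_equal(gain, 0.03 * 0.59 * 6.2e9, tolerance = 1e-9) # 1.0974e8 nt
  # 50% -> 51% over a 1 Mb genome
  b <- base_composition(c(A = 25, C = 25, G = 25, T = 25))
  a <- base_composition(c(A = 25.5, C = 24.5, G = 24.5, T = 25.5))
  e <- at_enrichment(b, a, genome_bp = 1e6)
  expect_equal(e$fold, 1.02)
  expect_equal(e$absolute_gain, 1e4)
  expect_error(at_enrichment(base_composition(c(A = 0, C = 50, G = 50, T = 0)),
                             same), "zero")
})
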