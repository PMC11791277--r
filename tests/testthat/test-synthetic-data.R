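test_that("hotspot template places RAS codons at their CDS positions", {
  ref <- hotspot_ref(seed = 7)
  expect_equal(substr(ref$bases, 31, 33), "GCC")  # Ala11
  expect_equal(substr(ref$bases, 34, 36), "GGC")  # Gly12
  expect_equal(substr(ref$bases, 37, 39), "GGT")  # Gly13
  expect_equal(substr(ref$bases, 67, 69), "CTG")  # Leu23
  expect_equal(substr(ref$bases, 181, 183), "CAG") # Gln61
  expect_error(reference_spec(100, hotspot_template = TRUE), "183")
})

test_that("reference generator hits the GC target and degenerate cases", {
  r <- make_reference(reference_spec(1000, gc_target = 0.591, seed = 1))
  gc <- attr(r, "gc_realized")
  expect_gte(gc, 0.571); expect_lte(gc, 0.611)
  at_only <- make_reference(reference_spec(100, gc_target = 0))$bases
  expect_true(grepl("^[AT]+$", at_only))
  gc_only <- make_reference(reference_spec(100, gc_target = 1))$bases
  expect_true(grepl("^[GC]+$", gc_only))
  # determinism and sensitivity to seed
  expect_identical(make_reference(reference_spec(200, 0.4, seed = 11))$bases,
                   make_reference(reference_spec(200, 0.4, seed = 11))$bases)
  expect_false(identical(make_reference(reference_spec(200, 0.4, seed = 11))$bases,
                         make_reference(reference_spec(200, 0.4, seed = 12))$bases))
})

test_that("zero-rate reads are exact reference substrings", {
  ref <- hotspot_ref()
  rs <- simulate_reads(ref, rate = 0, n_reads = 50, read_len = 60, seed = 3)
  for (i in seq_along(rs$sequences))
    expect_identical(rs$sequences[i],
                     substr(ref$bases, rs$offsets[i], rs$offsets[i] + 59))
})

test_that("read simulator reproduces its global substitution rate", {
  ref <- make_reference(reference_spec(150, gc_target = 0.5, seed = 2))
  q <- 0.01; n <- 10000; len <- 100
  rs <- simulate_reads(ref, rate = q, n_reads = n, read_len = len, seed = 5)
  mism <- sum(vapply(seq_len(n), function(i) {
    sum(strsplit(rs$sequences[i], "")[[1]] !=
          strsplit(substr(ref$bases, rs$offsets[i], rs$offsets[i] + len - 1),
                   "")[[1]])
  }, numeric(1)))
  N <- n * len
  expect_lt(abs(mism - N * q), 3 * sqrt(N * q * (1 - q)))
})

test_that("FASTQ output is byte-identical under a fixed seed", {
  ref <- hotspot_ref()
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(ref, 0.01, n_reads = 100, read_len = 80,
                             seed = 42), f1)
  write_fastq(simulate_reads(ref, 0.01, n_reads = 100, read_len = 80,
                             seed = 42), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_fastq(f1)
  expect_equal(length(rt$sequences), 100)
  expect_equal(rt$offsets,
               simulate_reads(ref, 0.01, n_reads = 100, read_len = 80,
                              seed = 42)$offsets)
})

test_that("read simulator validates its spectrum and probabilities", {
  ref <- hotspot_ref()
  bad <- matrix(1, 4, 4) # rows do not sum to 1 over alternatives
  expect_error(simulate_reads(ref, 0.01, spectrum = bad, n_reads = 10,
                              read_len = 50), "sum")
  expect_error(simulate_reads(ref, 1.5, n_reads = 10, read_len = 50), "\\[0, 1\\]")
  expect_error(simulate_reads(ref, 0.01, n_reads = 10, read_len = 500))
})

test_that("composition pair realizes the requested A+T fold exactly", {
  base <- c(A = 30, C = 20.5, G = 20.5, T = 29) # A+T = 59%
  pair <- simulate_composition_pair(base, 1.03)
  expect_equal(sum(pair$after), 100, tolerance = 1e-12)
  expect_equal(attr(pair$after, "at_percent"), 59 * 1.03) # 60.77
  id <- simulate_composition_pair(base, 1.0)
  expect_equal(as.numeric(id$after), as.numeric(id$before))
  expect_error(simulate_composition_pair(base, 2), "above 100")
  # round trip through the enrichment analysis
  expect_equal(at_enrichment(pair$before, pair$after)$fold, 1.03,
               tolerance = 1e-12)
})

test_that("cohort generator gives exact mutant counts and paired rows", {
  co <- simulate_cohort(135, seed = 1)
  per <- co[!duplicated(co$patient_id), ]
  expect_equal(sum(per$KRAS == "mutant"), 39)
  expect_equal(sum(per$BRAF == "mutant"), 19)
  expect_equal(sum(per$PI3K == "mutant"), 16)
  expect_true(all(table(co$patient_id) == 2))
  expect_true(all(table(co$patient_id, co$tissue) == 1))
  all_wt <- simulate_cohort(20, prevalence = c(KRAS = 0), seed = 2)
  expect_true(all(all_wt$KRAS == "WT"))
})

test_that("cohort Tm shift concentrates at the injected effect", {
  co <- simulate_cohort(1000, prevalence = c(KRAS = 0.5), tm_wt = 78.7,
                        delta_tm_mut = 1.3, noise_sd = 0.1, seed = 3)
  mut_tumor <- co$tm[co$tissue == "tumor" & co$KRAS == "mutant"]
  healthy <- co$tm[co$tissue == "healthy"]
  expect_lt(abs((mean(mut_tumor) - mean(healthy)) - (-1.3)), 0.02)
})
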