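# Shared fixtures and independent oracles.

# RAS-like 183-nt CDS with the hotspot codon template (Gly12 = GGC at nt
# 34-36, Gly13 = GGT at 37-39, Gln61 = CAG at 181-183).
hotspot_ref <- function(seed = 7, length = 183) {
  make_reference(reference_spec(length, gc_target = 0.55,
                                hotspot_template = TRUE, seed = seed))
}

# Brute-force mutation-matrix oracle: per-read, per-base double loop,
# deliberately naive and independent of the package's tally path.
oracle_tally <- function(sequences, offsets, ref_bases) {
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, 4, 4, dimnames = list(ref = bases, obs = bases))
  for (i in seq_along(sequences)) {
    rd <- strsplit(sequences[i], "")[[1]]
    for (j in seq_along(rd)) {
      rb <- substr(ref_bases, offsets[i] + j - 1, offsets[i] + j - 1)
      counts[rb, rd[j]] <- counts[rb, rd[j]] + 1L
    }
  }
  counts
}

# Naive per-base mismatch fraction of full-length products.
oracle_mismatch_fraction <- function(products, ref_bases) {
  total <- 0L; mism <- 0L
  for (p in products) {
    for (j in seq_len(nchar(ref_bases))) {
      total <- total + 1L
      if (substr(p, j, j) != substr(ref_bases, j, j)) mism <- mism + 1L
    }
  }
  mism / total
}

# Count substitution classes (e.g. "C>T") of products vs the reference.
substitution_counts <- function(products, ref_bases) {
  ref <- strsplit(ref_bases, "")[[1]]
  tab <- table(unlist(lapply(products, function(p) {
    obs <- strsplit(p, "")[[1]]
    d <- which(obs != ref)
    if (!length(d)) return(character(0))
    paste0(ref[d], ">", obs[d])
  })))
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       obs = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$obs, ]
  out <- stats::setNames(rep(0L, nrow(pairs)),
                         paste0(pairs$ref, ">", pairs$obs))
  out[names(tab)] <- as.integer(tab)
  out
}
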