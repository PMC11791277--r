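# mutascope

Simulation and detection of dNTP-imbalance-driven CG>TA mutagenesis.

When the intracellular dTTP pool greatly exceeds dCTP, polymerases
increasingly accept the dG:dT mispair. Because the mispair forms while
copying either strand, it surfaces as both C>T and G>A on the reported
strand — the CG>TA transition class that dominates oncogenic RAS mutations
at codons 12, 13 and 61. Each such transition removes one hydrogen bond
from the duplex (G:C pairs have 3, A:T pairs 2), lowering the melting
temperature (Tm) of mutant alleles and making them detectable by
melting-curve analysis and by differential-denaturation PCR.

`mutascope` is an R package for scientists studying this chain. It
provides, end to end and fully testable on synthetic data:

- **Error-prone PCR simulation** under unequal dNTP pools. Opposite
  template base *b*, base *x* incorporates with weight
  `[dNTP_x]` (Watson–Crick partner) or `δ(b,x)·[dNTP_x]` (mispair);
  products are sampled by strand-alternating lineage walks
  (`dntp_pool()`, `misincorporation_model()`, `simulate_pcr()`).
- **Mutation-spectrum analysis**: 4×4 substitution matrices normalized by
  per-reference-base coverage, per-site frequencies, hotspot-codon
  summaries (codon *k* = CDS nt 3k−2..3k), base composition and A+T
  enrichment (`tally_matrix()`, `site_frequency()`,
  `hotspot_codon_report()`, `at_enrichment()`).
- **Thermodynamic screening**: hydrogen-bond counting, the
  Marmur–Schildkraut Tm estimate
  `Tm = 81.5 + 16.6·log10([Na+]) + 0.41·GC% − 675/L` (one CG>TA transition
  in an L-nt window shifts Tm by exactly −0.41·100/L °C), melting-curve
  synthesis with derivative peak calling, Tm-shift genotyping, and
  denaturation-gradient selection of AT-rich alleles (`tm_estimate()`,
  `melt_curve()`, `classify_sample()`, `td_selection()`).
- **Variant consequences**: codon-level annotation with the standard
  genetic code, RAS hotspot flags, the codon-12 transforming rule
  (any residue except Gly/Pro), and ΔΔG stability classes with strict
  ±3 kcal/mol thresholds (`annotate()`, `is_transforming()`,
  `classify_stability()`).
- **Cohort screening**: mutation prevalence with exact fractions and
  half-up display percentages, a paired one-sided sign-flip permutation
  test on tumor-vs-healthy Tm, and 2^(−ΔΔCt) fold changes
  (`prevalence()`, `tm_shift_test()`, `ddct_fold()`).
- **Synthetic-data generators** for all of the above with known ground
  truth (`make_reference()`, `simulate_reads()`, `simulate_cohort()`,
  `simulate_composition_pair()`), and a seeded, manifest-writing pipeline
  (`run_pipeline()`; thin CLI wrapper in `inst/scripts/mutascope`).

## Worked example

```r
library(mutascope)

# A RAS-like 576-nt CDS with hotspot codons at their canonical positions
ref <- make_reference(reference_spec(576, gc_target = 0.591,
                                     hotspot_template = TRUE, seed = 103))
substr(ref$bases, 34, 36)
#> [1] "GGC"          # the Gly12 codon

# Error-prone PCR at the strongest bias (dTTP/dCTP = 100)
prods <- simulate_pcr(ref, dntp_pool(dATP = 50, dCTP = 10, dGTP = 50,
                                     dTTP = 1000),
                      misincorporation_model(),
                      pcr_run(cycles = 30, n_products = 2000, seed = 105))
mutation_frequency(prods, ref)
#> [1] 0.07588455    # ~7.6% of bases mutated at the 100:1 bias

m <- tally_matrix(prods, ref)
round(100 * c(CtoT = m$frequency["C", "T"], GtoA = m$frequency["G", "A"]), 2)
#>  CtoT  GtoA
#> 12.66 12.75       # CG>TA transitions dominate, balanced across strands

# One CG>TA transition in a 30-nt window loses one H-bond and 1.37 degC
win <- substr(ref$bases, 25, 54); mut <- win; substr(mut, 10, 10) <- "T"
hydrogen_bond_count(win) - hydrogen_bond_count(mut)
#> [1] 1
tm_estimate(mut) - tm_estimate(win)
#> [1] -1.366667

# Cohort screen: 135 patients, planted prevalences, paired Tm shift
cohort <- simulate_cohort(135, seed = 1)
prevalence(cohort, "KRAS")
#> <prevalence_report> KRAS: 39/135 (28.9%, displayed ~29%)
tm_shift_test(cohort, gene = "KRAS", n_perm = 9999, seed = 2)[c("statistic",
                                                                "p_value")]
#> $statistic
#> [1] -1.295793    # mutant tumors melt ~1.3 degC below healthy tissue
#> $p_value
#> [1] 1e-04
```

The mutation frequency rises monotonically with the [dTTP]/[dCTP] ratio
(Spearman ρ = 1 across the 1–100 ratio sweep), ≥ 99% of simulated
substitutions are C>T/G>A, and the 1.3 °C Tm drop of mutant tumors is
called at the 0.4 °C threshold — see `vignettes/` for the models behind
these numbers and their assumptions.

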