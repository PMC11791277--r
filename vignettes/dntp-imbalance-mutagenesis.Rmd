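---
title: "From dNTP-pool imbalance to CG>TA detection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dNTP-pool imbalance to CG>TA detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutascope)
```

## The problem

Imbalanced intracellular dNTP pools are mutagenic. When dTTP greatly
exceeds dCTP, a replicating polymerase increasingly accepts the dG:dT
mispair; because the mispair forms while copying either strand of a duplex,
the lesions surface on the reported (sense) strand as both C>T and G>A —
the CG>TA transition class that dominates oncogenic RAS mutations at
codons 12, 13 and 61. Every CG>TA transition also removes exactly one
hydrogen bond from the duplex (G:C has three, A:T two), which lowers the
melting temperature and makes mutant alleles detectable by melting-curve
analysis and by differential-denaturation PCR.

`mutascope` implements this whole chain at desk scale: a biased-dNTP PCR
simulator, substitution-spectrum and hotspot analyses, thermodynamic
screening, codon-level consequence annotation, and cohort-level
statistics — plus generators that produce every input with known ground
truth, so each stage is testable end to end without external data.

## The misincorporation model

Opposite a template base $b$, the probability of incorporating base $x$ is

$$P(x \mid b) = \frac{w(x)}{\sum_y w(y)}, \qquad
  w(x) = \begin{cases}[\mathrm{dNTP}_x] & x \text{ is the Watson–Crick partner}\\
  \delta(b, x)\,[\mathrm{dNTP}_x] & \text{otherwise,}\end{cases}$$

where $\delta(b,x) \ge 0$ is the polymerase discrimination factor. The
default model sets $\delta(\mathrm{G,T}) = \delta(\mathrm{C,A}) = 10^{-4}$
(the dG:dT mispair and its antisense image) and zero elsewhere. The factor
is the model's single free kinetic parameter: no published rate constants
pin it down, and all claims the package tests are relative (ratio
proportionality, spectrum dominance, strand symmetry), which a single
shared factor reproduces. With dCTP at 10 µM and dTTP at 1000 µM the
per-site G>A probability per copy event is
$0.1/(10 + 0.1) \approx 9.9\times10^{-3}$; at equal concentrations it
falls to $\sim 10^{-4}$, which is what makes the mutation load proportional
to the [dTTP]/[dCTP] ratio.

### Lineage sampling

A full population simulation doubles molecule counts every cycle, which is
both infeasible and unnecessary: only the mutation history of the sampled
final molecules matters. `simulate_pcr()` therefore walks one lineage per
reported product: the lineage starts from either strand of the
double-stranded template with probability 1/2, and at each of the `cycles`
(default 50) thermal cycles it is copied with probability `dup_prob`
(default 0.9). Every copy event applies the misincorporation model
position-wise and flips the tracked strand; lineages ending antisense are
complemented back to template orientation. The random start strand matters:
sense-only starts would make odd-numbered copy events (which create G>A)
systematically outnumber even ones, biasing the spectrum by a few percent
for no chemical reason.

Misincorporated bases are never proofread (Taq has no 3'→5' exonuclease),
there is no indel model (the analyses are substitution-only amplicon
analyses), and no stalling/yield model — the reduced PCR efficiency seen at
extreme bias is out of scope.

Note on strand symmetry: C>T and G>A *counts* are only expected to be
equal on a reference with equal C and G content; the strand-symmetric
quantity is the per-coverage *rate*, which is also how the mutation
matrices are normalized.

## Spectrum analysis

`tally_matrix()` produces the full 4×4 (reference base × observed base)
count table with per-reference-base coverage; frequencies are
counts/coverage, so they are comparable across references of different
composition. All 12 off-diagonal substitution types are reported without
pyrimidine-strand collapsing, because the both-strand mechanism predicts
C>T and G>A separately. Zero-coverage positions are reported as missing
(`NA`), never as a frequency of 0. Hotspot summaries average the three
per-site frequencies of each codon, with codon $k$ spanning CDS
nucleotides $3k-2..3k$ (codon 12 = nt 34–36, codon 13 = nt 37–39,
codon 61 = nt 181–183; 1-based inclusive coordinates throughout).

`at_enrichment()` projects a composition shift onto a genome:
$\mathrm{fold} = \mathrm{AT\%}_{after}/\mathrm{AT\%}_{before}$ and
$\mathrm{gain} = (\mathrm{fold}-1) \cdot \mathrm{AT\%}_{before}/100 \cdot
\mathrm{genome\ bp}$. The default genome size is $6.2\times10^9$ bp (a
diploid human genome); a 1.03-fold shift on a 59% A+T baseline gains
$\approx 1.1 \times 10^8$ nucleotides. `simulate_composition_pair()`
constructs the paired compositions so that the treated A+T percentage is
*exactly* `fold_at` times the baseline's and the G+C share fills the
remainder (G:C ratio preserved); scaling A and T and then renormalizing
the whole vector would silently shrink the realized fold (1.03 requested,
1.012 realized) and break the round trip with `at_enrichment()`.

## Thermodynamic screening

The melting model is the Marmur–Schildkraut GC-content formula with salt
and length corrections:

$$T_m = 81.5 + 16.6\log_{10}[\mathrm{Na}^+] + 0.41\,\mathrm{GC\%} - 675/L.$$

It is deliberately simple: every quantity the package asserts is a shift
or an ordering, and under this formula one CG>TA transition in a window of
length $L$ shifts $T_m$ by exactly $-0.41 \times 100/L$ °C (−1.37 °C for a
30-nt window), mirroring the loss of one hydrogen bond. The formula is
restricted to $L \ge 14$; a nearest-neighbor model is a possible extension
point for short probes but is not needed for any supported analysis. No
attempt is made to reproduce absolute instrument $T_m$ readings
(dye/buffer effects are uncalibrated). One consequence worth knowing: from
gene-wide GC contents of 59.1% vs 37.6% the formula predicts an 8.8 °C
offset between a GC-rich and an AT-rich amplicon, while measured RAS
melting profiles differ by about 5 °C — amplicon-local GC content differs
from the gene-wide value, so only the sign and ordering of such offsets
are asserted anywhere.

Defaults: `na_molar = 0.05` M, `sigmoid_width = 0.3` °C, and
`delta_tm_threshold = 0.4` °C — just below the smallest wild-type-vs-mutant
gap in the motivating screen (83.7 − 83.2 = 0.5 °C), so a single-transition
shift is called mutant while grid noise is not.

`melt_curve()` synthesizes fluorescence as a weighted sum of two-state
sigmoids, $F(T) = \sum_i w_i\,\sigma((T_{m,i} - T)/\text{width})$, takes
the negative derivative by central differences and calls $T_m$ as the
derivative argmax on the discrete grid (default step 0.1 °C, no
interpolation — peak recovery is therefore exact to one grid step, which
is all the classification threshold needs). `td_selection()` models
differential-denaturation PCR as a hard step: a sequence is recovered at
gradient temperature $T$ iff its denaturation temperature (its $T_m$
estimate) is ≤ $T$, which reproduces the all-or-nothing lanes of the
technique and guarantees nested recovery sets; a logistic soft margin is
available via `soft_width` (one shared uniform draw per sequence keeps the
soft variant nested too).

## Variant consequences and stability

`annotate()` translates the affected codon with the standard genetic code
and flags hotspots (codons 12/13/61), synonymous changes, and CG>TA-class
substitutions. The transforming rule is deliberately narrow: only codon-12
substitutions to anything but glycine or proline return `TRUE`, because
that is the established focus-formation result for Gly12; codons 13 and 61
are surfaced through the hotspot flag without a transformation claim.
Stability classification uses strict thresholds — stabilizing below
−3 kcal/mol, destabilizing above +3, neutral otherwise (±3 exactly is
neutral) — and `count_by_class()` always reports all three classes.
Multi-nucleotide variants are handled as independent single-nucleotide
annotations.

## Cohort statistics

`tm_shift_test()` replaces an ANOVA-with-post-hoc design with a one-sided
paired sign-flip permutation test on the per-patient difference
(tumor $T_m$ − healthy $T_m$): exact under the null of no shift,
assumption-light, and deterministic under a seed. The p-value uses the
add-one convention $p = (1 + \#\{\bar d^{*} \le \bar d\})/(B + 1)$
(never zero); the default $B$ is 9999. Pairing is per patient — each
tumor is compared to its own healthy tissue — and unpaired patients are a
hard error listing the offending ids. Prevalence reports keep the exact
fraction and additionally display a half-up integer percentage (39/135 →
28.9% → "29%"). `ddct_fold()` is the standard
$2^{-\Delta\Delta C_t}$ arithmetic.

## What the generators emulate — and what they do not

`make_reference()` emulates a RAS-like coding sequence: the hotspot
template hard-codes GCC-GGC-GGT at codons 11–13 and CTG/CAG at codons
23/61, so the canonical variant examples (C32>T, G34>T, G69>A) replay
exactly; the remaining positions are i.i.d. draws hitting the GC target to
within rounding. Real RAS sequences are not embedded — absolute gene-wide
GC values (59.1%/37.6%) are reproducible only with user-supplied real
sequences — so all sequence-level claims are relative. `simulate_reads()`
produces ungapped substrings with a known substitution spectrum, constant
Q37 qualities, no adapter/duplicate/indel structure, and no
quality-dependent error model: passing tests demonstrate correct recovery
of a *known* spectrum, not robustness to real library artifacts, which is
why no quality filtering exists downstream either. `simulate_cohort()`
plants exact mutant counts (`round(n × prevalence)`) and Gaussian $T_m$
noise (default 0.1 °C) around a 78.7 °C wild type with a 1.3 °C mutant
shift — the Gly12 vs Val12 gap; real melting measurements have
batch/instrument structure this does not model.

## Problem sizes and numerical choices

The test suite and the acceptance script run the stochastic checks at
sizes chosen to make the binomial error bars decisively smaller than the
effects under test: the ratio sweep uses 5 pools × 2000 products ×
30 cycles on the 576-nt template (~150k transitions pooled); rate recovery
uses 50,000 reads × 150 nt (3 standard errors ≈ 0.01% around a 0.63–0.78%
rate); the permutation-test calibration uses 200 null cohorts at $B = 999$
and a Kolmogorov–Smirnov check at $\alpha = 0.01$; power at the planted
1.3 °C / 0.1 °C / n = 50 configuration is estimated over 100 replicates.
All generators restore the caller's RNG state and are pure functions of
their arguments including the seed; the pipeline derives per-stage seeds
from one global seed by a fixed counter scheme so stages are independently
reproducible, and its manifest records an md5 per artifact so identical
configs are verifiably byte-identical.

## Known limitations

- The Tm model is composition-only: no nearest-neighbor stacking, no
  mismatch-specific destabilization, no instrument calibration.
- The PCR simulator has no amplification-efficiency or yield model, so
  gel-intensity-style observations have no counterpart here.
- Whether a per-base mutation frequency or a per-clone mutated fraction is
  the right summary at extreme bias is genuinely ambiguous in the
  motivating data ("~7.7%" vs "2–3 substitutions per 576-nt clone");
  `mutation_frequency()` reports the per-base definition and leaves the
  discrepancy open.
- Sequencing-error baseline subtraction (the ~0.65% untreated-level rate)
  is left to the user; all reported frequencies are raw.
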