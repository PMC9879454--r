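---
title: "Models and methods behind tyshuffle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tyshuffle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyshuffle)
```

## Scope

`tyshuffle` models what happens to a hybrid diploid yeast genome when
double-strand breaks are targeted into every Ty1 retrotransposon at once, and
how those outcomes are read back out of sequencing signals. Three signal
layers are modeled: per-SNP allele read depth (the primary event-calling
substrate), long-read diagnostic-SNP evidence inside hybrid Ty elements, and
fluctuation-assay colony counts. Raw reads, alignment, and real genome
coordinates are out of scope: the genome model reproduces counts, families,
arm placement and scale, not real annotations.

## The genome model

The simulated diploid mirrors a cross between two sequence-diverged haploids.
Chromosome lengths and centromere positions follow the 16 budding-yeast
reference chromosomes (~12.1 Mb per haploid set); a `mini` profile scales
each chromosome into 100–500 kb (about 4 Mb total) for fast tests. One
homolog class (`W`) carries 37 full Ty1 and 15 Ty2 elements, the other (`Y`)
17 Ty1 and 9 Ty2, plus 40 solo deltas each, placed uniformly at random
outside centromeres — so most elements are non-allelic between the parents,
as in the real hybrid. Full elements span 5.9–6.3 kb, solo deltas exactly
330 bp; every full Ty1 carries the Cas9 target, whose cut site sits 2,180 bp
from the element's 5' end. Heterozygous SNPs (55,000 by default; 2,000 for
`mini`) are laid on a jittered grid outside Ty spans, which bounds the
largest inter-SNP gap at roughly twice the mean spacing — a deliberate
idealization (real SNP maps have deserts) that makes breakpoint-window
coverage testable.

## Karyotypes and mechanism operations

A karyotype is a list of chromosome molecules, each an ordered list of
*segments* of parental material (homolog, chromosome, start, end,
orientation). All mechanism operations are splice operations on segment
lists; per-SNP copy number is interval arithmetic over segments, and a
brute-force membership oracle checks it in the tests.

Junction placement inside the recombining elements is abstracted to the
element's 5' boundary: heterozygous SNPs never fall inside Ty spans, so any
junction within the elements yields the same dosage profile. Consequences of
each mechanism:

* **SSA pop-out** — element body replaced by one solo delta; dosage-silent.
* **Unequal crossover** (same homolog, arm and orientation) — deletes or
  tandem-duplicates the inter-element interval (I-DEL / I-DUP). A
  direct-orientation pair straddling the centromere is *not* accepted here:
  that geometry is the centric-circle (or dicentric) route.
* **Intrachromatid circle** (direct repeats on opposite arms) — the centric
  circle is retained, both acentric arms lost: double terminal deletion.
* **Isochromosome** (inverted repeats on opposite arms) — one arm mirrored,
  the other lost: coupled T-DUP and T-DEL on the same chromosome.
* **Inversion** (inverted repeats, one arm) — segment between the elements
  reversed in place; dosage-silent, two novel junctions. The operation works
  on the parental-coordinate block so applying it twice restores the
  original molecule.
* **Translocations** (non-homologous chromosomes) — balanced: both
  reciprocal products kept, dosage-silent; unbalanced (and BIR): one
  monocentric recombinant kept with an intact copy of its suffix donor,
  giving the coupled T-DEL (prefix donor) + T-DUP (suffix donor) signature.
  Eligibility requires both cuts on the same arm type so both products are
  monocentric; junction orientation is otherwise abstracted. Mixed-arm
  direct fusions are modeled separately as flagged dicentrics, which the
  signal synthesizer refuses — such products are selected against in vivo.
* **Allelic events** — crossover/BIR homozygose from the breakpoint to the
  telomere (T-LOH, dosage-conserving); conversion homozygoses an
  interstitial tract (I-LOH). A tract running past the telomere is clipped
  and relabeled T-LOH with a warning.
* **Aneuploidy** — monosomy, trisomy, uniparental disomy on whole molecules.

`simulate_isolate()` composes mechanisms drawn by weight. The default
weights are the combined event tallies of the long-term and transient
induction cohorts the package models (deletions 17, duplications 5, circles
2, isochromosomes 3, inversions 3, simple translocations 23 split
18 unbalanced / 4 BIR / 1 balanced, I-LOH 28, T-LOH 29 split 20 crossover /
9 BIR, monosomy 17, trisomy 1, UPD 4, one pop-out, one Ty-Ty conversion);
terminal LOH loses the W haplotype with probability 24/25, the observed
direction bias, while conversions are unbiased. Ty-Ty mechanisms break a
Cas9-target-bearing Ty1 and choose the partner family with probabilities
118:5:1 (Ty1:Ty2:delta over 124), the observed partner tally. Events within
one isolate are placed on disjoint chromosomes so that each truth record's
expected dosage class is well defined; colliding events produce the complex
multi-transition patterns that the per-event taxonomy deliberately does not
cover. A draw with no eligible participants is retried up to 20 times, then
skipped with a message.

Two tract-length scales are distinguished, both geometric: Ty-internal
conversion tracts default to mean 2 kb (they live inside a 6-kb element),
while allelic I-LOH tracts default to mean 30 kb, matching the scale of the
interstitial LOH events the depth-based caller can actually see. A single
2-kb scale for both — a literal reading of the one stated default — would
put nearly every allelic conversion below the caller's minimum segment
support and make the I-LOH pathway untestable, so the package treats the
stated 2-kb figure as the Ty-internal scale.

## Read-depth synthesis and the caller

For an allele at copy number $c$ the read count is Poisson with mean
$\bar D/2 \cdot c$, where $\bar D$ is the mean total site depth (default
40×); a negative-binomial option (dispersion parameter `nb_dispersion`)
exists for robustness checks. The ratio of coverage divides each count by
the realized genome-wide mean site coverage, so RC is invariant to global
depth rescaling and sits near 0.5 / 0 / 1.0 for heterozygous / lost /
duplicated alleles.

The caller median-smooths each homolog's RC series (window 11 SNPs), maps it
to dosage states by thresholds 0.25 and 0.75 (midpoints between the ideal
levels), merges runs, and absorbs runs under the minimum support (5 SNPs
*and* 10 kb) into their larger neighbor. Joint (W, Y) state regions are then
classified: reciprocal 0/2 regions are LOH (terminal vs interstitial by
telomere contact), non-reciprocal regions are DEL/DUP, single
whole-chromosome regions are monosomy/trisomy/UPD, double terminal
deletions on one homolog merge into CIRCLE, and a coupled terminal
deletion/duplication on opposite arms into ISO. Whole-chromosome calls
suppress overlapping segment calls; ISO recognition precedes translocation
pairing, which then greedily pairs each T-DEL with an unpaired T-DUP on a
different chromosome (ties by chromosome order, then coordinate).

One numerical subtlety: a running median biases segment edges inward by
about one SNP, because at the boundary the smoothed value on the duplicated
homolog is the *minimum* of the half-window of high values, which dips under
the 0.75 threshold ~20% of the time at 40× depth. Call edges are therefore
refined outward, up to half a smoothing window, while the raw per-SNP state
still matches the call's pattern; for LOH calls only the lost allele's exact
zero is required, since that is the sharp signal. No thresholds are changed
by the refinement.

Breakpoints are reported per the windowing rules: I-LOH spans run from the
last flanking heterozygous SNP to the first on the other side; all other
edges get a 20-kb window centered at the midpoint between the last unaltered
and first altered SNP, clipped at chromosome ends. The 20-kb rule is stated
for LOH breakpoints in the source analysis; this package applies it to
dosage-event edges as well, which keeps every edge's report format uniform.

### What a green truth-recovery test establishes

`expected_observable_class()` maps each truth event onto the dosage
signature it encodes *at the caller's resolution*, using only the true
affected spans and the SNP map: an altered span with fewer than 5 SNPs or
under 10 kb is silent; an event whose flank on one side is unresolvable
degrades to the terminal class (an I-DEL with no distal SNPs *is* a T-DEL in
dosage space), and with no resolvable flank to the whole-chromosome class.
The acceptance experiment (200 isolates × 3 events, mini profile, 40×
Poisson noise) requires ≥95% of visible events to receive exactly that
class with breakpoint windows containing the true breakpoints, and zero
calls on 50 event-free isolates; measured recovery is 0.97–1.00 by seed.
This establishes that the caller inverts the simulator's own signal model —
not that it would perform identically on real data, where depth is
GC-biased and overdispersed, SNP density is uneven, and events collide.

## Cohort statistics

Exact tests are implemented by direct enumeration — Fisher's 2×2 by summing
hypergeometric point masses no larger than the observed table's
(probability-mass two-sided convention), the direction-bias test by the
binomial analogue — and are oracle-checked against `stats::fisher.test` and
`binom.test` to 1e-12 across dense table grids. The goodness-of-fit and
region chi-squares are the textbook formulas; the region test defaults to
Yates' continuity correction because that is the only reading that
reproduces the printed p = 0.15 for 2-of-20 mutations in 2.5% of the genome
(uncorrected gives ≈ 0.03). The intra/interchromosomal pair enumeration uses
explicit detectability rules (same-homolog same-chromosome pairs need a SNP
in — or, for opposite-arm pairs, distal to — the interval; non-homologous
pairs always detectable; allelic pairs excluded); the source supplement's
exact rules are unavailable, so the printed 0.10 expectation is a
plausibility anchor, not a target. The hotspot test is a one-sided binomial
tail against uniform element usage with optional Bonferroni correction; the
source does not name its hotspot statistic, so its printed hotspot p-values
are likewise not targets.

## Rates

Per-division rates for induced cohorts are event counts over isolates
(events are assumed to arise in the single induced division). Fold changes
round to two significant figures with halves away from zero — the convention
that reproduces every printed fold, including 22.5 → 23, where R's
round-half-even `signif()` would give 22. The fluctuation estimator is the
Lea–Coulson method of the median: solve $\tilde r/m - \ln m - 1.24 = 0$ by
bracketed root-finding (tolerance 1e-9), then rate $= m/N_t$. The simulator
uses synchronous doublings with clonal expansion of mutants, the simplest
discretization; plating efficiency and post-plating growth are out of scope.
The median method has a hard resolution floor: for expected mutation numbers
$m < \ln 2$ the zero-culture fraction $e^{-m}$ exceeds one half, the median
count is 0, and the estimator returns a flagged zero by definition — so
recovery bounds are only meaningful above that floor (the acceptance suite
asserts ×/÷1.5 recovery for $m \in \{1, 2, 5, 10\}$ and the flagged zero at
$m = 0.5$).

## Long-read tract mapping

Within a hybrid Ty element, each diagnostic SNP column is voted across
reads: the column is assigned to the parent supported by at least two-thirds
of non-missing calls (closed inequality, missing calls excluded from the
denominator), otherwise ambiguous. The donor tract is the maximal
minority-parent run nearest the cut site, with ambiguous columns transparent
to run construction. A tract extending to both sides of the cut is labeled
`DSBR_like`, one side `BIR_like`, no tract `indeterminate` — suggestive
labels only, since mismatch correction during BIR strand invasion can also
displace the observed transition. Tripartite hybrids are represented as two
successive two-parent calls.

## Known limitations

* Event collisions (multiple events on one chromosome) are excluded from the
  default simulator, so the complex multi-transition patterns seen in real
  isolates are not generated or classified.
* The depth model is unbiased Poisson/NB per site; no GC or mappability
  structure.
* Ty placement is uniform outside centromeres; real Ty1 insertion has strong
  positional preferences (e.g. upstream of tRNA genes), and the mini profile
  is ~3× denser in elements per Mb than the genome it mimics — density-
  sensitive statistics (chance Ty-overlap of breakpoints) are only
  meaningful at the full profile.
* Balanced translocations, inversions and pop-outs are dosage-silent by
  construction and only observable through the long-read layer, as in the
  modeled study.
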