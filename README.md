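# tyshuffle

Simulation and dosage-based calling of Ty1-mediated genome rearrangements in
hybrid diploid yeast.

## The problem

Ty1 retrotransposons (~6 kb, flanked by 330-bp "delta" LTRs) are the largest
dispersed repeat family in *Saccharomyces cerevisiae*. Double-strand breaks
inside Ty1 elements are repaired by homologous recombination, and because the
elements are non-allelic repeats, repair can use the "wrong" copy: unequal
crossovers delete or duplicate the interval between elements, exchanges
between elements on opposite arms form centric circles or isochromosomes,
exchanges between non-homologous chromosomes form translocations, and
allelic repair produces terminal or interstitial loss of heterozygosity
(T-LOH / I-LOH). In a hybrid diploid heterozygous for ~55,000 SNPs (one
parental homolog set carrying 37 Ty1 + 15 Ty2, the other 17 Ty1 + 9 Ty2),
every one of these outcomes leaves a characteristic footprint in the
per-SNP **ratio of coverage**

RC(s) = (reads supporting allele at SNP s) / (genome-wide mean total site
coverage),

so RC ≈ 0.5 for an unaltered heterozygous allele, ≈ 0 for a lost allele,
and ≈ 1.0 for a duplicated one.

`tyshuffle` packages that whole analysis loop for a diploid in which Cas9 is
targeted to all Ty1 elements at once:

* **genome model** — a W303-1A × YJM789-like hybrid genome (chromosome
  lengths, centromeres, het-SNP map, per-homolog Ty/delta annotations),
  serialized as `chromosomes.tsv` + `ty.bed` (BED6+2) + `snps.tsv`;
* **simulator** — segmental karyotype operations for every recombination
  mechanism (SSA pop-out, unequal crossover, circle, isochromosome,
  inversion, balanced/unbalanced/BIR translocation, allelic crossover/BIR/
  conversion, monosomy/trisomy/UPD), composed at random into isolates, plus
  Poisson/negative-binomial read-count synthesis, long-read diagnostic-SNP
  matrices over hybrid Ty elements, and Luria–Delbrück fluctuation assays;
* **event caller** — RC smoothing, dosage-state segmentation, the full event
  taxonomy (T/I-LOH, T/I-DEL, T/I-DUP, CIRCLE, ISO, MONOSOMY, TRISOMY, UPD),
  20-kb breakpoint windows, T-DEL/T-DUP translocation pairing, and the
  4-class PCR diagnosis of haploid 5-FOA-resistant isolates;
* **statistics** — Ty-at-breakpoint association and hotspot tests,
  intra/interchromosomal pair enumeration with chi-square goodness of fit,
  exact Fisher and binomial tests (implemented by enumeration, oracle-checked
  against `stats`), per-division event rates and fold changes, and the
  Lea–Coulson method-of-the-median fluctuation-rate estimator;
* **long-read tract mapper** — per-SNP two-thirds majority voting across
  reads, conversion-tract construction, and a suggestive BIR-vs-DSBR label
  from tract sidedness relative to the cut site.

## Worked example

```r
library(tyshuffle)

g <- default_hybrid_genome(1, profile = "mini")   # fast 4-Mb test genome
k <- baseline_karyotype(g)

# a crossover at 300 kb on chromosome IV homozygoses the distal segment
ev <- apply_allelic_event(k, "IV", 300000, "crossover", lose = "W")
counts <- synthesize_snp_counts(ev$karyotype, sim_params(mean_depth = 40),
                                seed = 5)
call_events(counts, g)[, c("class", "chromosome", "homolog",
                           "bp1_start", "bp1_end")]
#>   class chromosome homolog bp1_start bp1_end
#> 1 T-LOH         IV       W    292537  312537
```

The caller reports a terminal LOH of the W haplotype on IV with a 20-kb
breakpoint window — which contains the true breakpoint at 300,000.

Published-scale arithmetic reproduces the printed numbers exactly:

```r
per_division_rate(12, 19)              # 0.632  simple translocations
fold_change(per_division_rate(12, 19), 3.79e-6)   # 170000 (fold over WT)
fold_change(3.6e-4, 1.5e-6)            # 240    guide RNA + galactose
gof_chisq(c(43, 52), c(0.10, 0.90))$p  # 2.2e-30  intrachromosomal excess
region_chisq(2, 18, 0.025)$p           # 0.152    mutations in T-LOH regions
```

## Command line

```sh
Rscript inst/cli/tyshuffle simulate --seed 7 --out-dir run --n-isolates 19
Rscript inst/cli/tyshuffle call --counts run/isolates/isolate_01.counts.tsv \
    --genome-dir run/genome --out-dir run
Rscript inst/cli/tyshuffle associate --events run/events.json \
    --genome-dir run/genome --out-dir run
Rscript inst/cli/tyshuffle stats --tallies tallies.json --out run/stats.json
Rscript inst/cli/tyshuffle rates --tally tally.json --out run/rates.json
Rscript inst/cli/tyshuffle map-ty --matrix run/tymatrix.tsv --out run/tract.json
Rscript inst/cli/tyshuffle report --run-dir run --out run/report.json
```

Every stage is seed-deterministic; `manifest.json` records md5 checksums of
all artifacts.

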