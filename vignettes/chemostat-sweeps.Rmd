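---
title: "Simulating and dissecting selective sweeps in a chemostat metagenome"
author: "poolsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and dissecting selective sweeps in a chemostat metagenome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweep)
```

## The problem

A clonal *E. coli* population held in a glucose-limited chemostat for 60
days accumulates thousands of mutations. Pooled ("metagenomic") sequencing
of the whole culture at ~800x depth, sampled at 11 time points, turns read
fractions into allele-frequency trajectories, and those trajectories carry
the population-genetic signal: multi-allele **soft sweeps** in the driver
genes of glucose-limitation adaptation (*rpoS*, *mglD*, *malT*), an
occasional single-allele **hard sweep** (*sdhC*-like), a negative
frequency-dependent lineage (*hfq*-like) that persists below fixation, a
fitness-neutral **mutator** that hitchhikes to high frequency, and a large
cloud of low-frequency passengers.

No raw reads are publicly deposited for this kind of experiment, so
`poolsweep` makes the entire analysis testable by pairing it with a
synthetic-data generator whose ground truth is known exactly. The package
has three layers:

1. **Generation** — a Wright–Fisher chemostat simulator (`run_simulation()`)
   and a pooled-sequencing simulator (`make_sample()`,
   `make_read_pairs()`).
2. **Primary data processing** — FASTQ quality trimming and PCR-duplicate
   removal (`trim_read()`, `dedup_pairs()`), and the pooled variant-calling
   filters with an exact analytic companion (`call_sample()`,
   `detection_probability()`).
3. **Population-genetic interpretation** — trajectory assembly and summary
   statistics (`build_table()`, `occurrence_spectrum()`, `gene_summary()`),
   cohort (linkage) clustering, hard/soft sweep classification and
   hitchhiker flagging (`detect_cohorts()`, `classify_gene_sweep()`,
   `detect_hitchhikers()`).

`run_pipeline()` chains all stages under one config with per-stage derived
seeds and a reproducibility manifest.

## The population model

The chemostat holds the population at constant size `N` with dilution rate
`D` (h^-1); at steady state growth balances washout, so the culture runs at

$$ g = \frac{24\,D}{\ln 2} \;\text{generations/day}, $$

i.e. about 3.46 generations/day at the experimental `D = 0.1` — roughly 208
Wright–Fisher generations over 60 days. Time is discretised to whole
generations; samples are taken at the generation nearest each sample day.

Each generation, genotype *i* with count \(n_i\) and fitness \(w_i\)
contributes offspring multinomially with probability \(\propto n_i w_i\);
population size is conserved exactly. Fitness is:

* **Drivers** — multiplicative \( \prod_g (1 + s_g) \) over *distinct*
  mutated driver genes. The benefit is loss-of-function-like: a second
  allele of the same gene adds nothing. This is what makes alleles of one
  gene mutually redundant and produces soft-sweep structure.
* **Negative frequency dependence** — a carrier of an *hfq*-like mutation
  has fitness multiplied by \( 1 + s_h - c\,x_h \) (clipped at 0), where
  \(x_h\) is the current carrier frequency. Against a neutral resident the
  deterministic recursion settles at \(x^\* = s_h/c\)
  (`freq_dep_recursion()`), and stochastic runs fluctuate around it without
  fixing — the below-fixation persistence seen for *hfq*.
* **Epistasis** — the frequency-dependent benefit is nullified on
  backgrounds already carrying a strong-driver mutation, mirroring the
  exclusion of *hfq* and *rpoS* mutations from the same genome.
* **Mutator** — fitness-neutral, but multiplies the genome-wide mutation
  rate by `mutator_fold` (default 100, matching the >100-fold elevation
  measured for such clones). It can only rise by hitchhiking.

New mutations arrive per genome per generation at rate
`mu * genome_length` (Poisson). Implementation detail: the per-genotype
event total is drawn as Poisson(offspring x rate) and each event creates
one new single-mutant offspring genotype; two hits landing in the same
individual in the same generation (probability \(O(U^2)\)) are realised as
two separate single mutants. Positions are uniform; the class (SNP, small
indel, large indel, duplication) is drawn from the fractions observed in
the experiment's mutation catalogue; SNP coding effects are *not* drawn
from a configured fraction but computed mechanistically, by strand-aware
codon translation against the synthetic genome (stop gains and start-codon
hits count as protein-altering). Small and large indels inside a coding
gene are treated as protein-disrupting, consistent with the experiment's
gene table including 1-bp coding indels among nonsynonymous changes.

### Default study conditions and why

| parameter | default | rationale |
|---|---|---|
| `N` | 1e6 | desk-scale stand-in for the real 1.6e10; drift and detection noise are therefore much stronger than in the culture |
| `genome_length` | 1e5 bp | ~1/46 of the *E. coli* genome; ~90% coding, matching the real coding fraction |
| `mu` | 1e-9 /bp/gen | upper range of *E. coli* per-base estimates; chosen so that strong driver genes accumulate several detectable alleles per run, reproducing multi-allele sweep structure at this N |
| `mutator_fold` | 100 | the measured >100-fold elevation |
| `dilution_rate` | 0.1 h^-1 | the experimental dilution rate |
| `sample_days` | 5,7,14,20,28,35,40,45,50,56,60 | 11 samples over 60 days; the exact days are not published, these are plausible and configurable |
| driver `s` | rpoS 0.12, mglD 0.10, malT 0.09, sdhC 0.07, malE 0.06 | free parameters (no published values); ordered so rpoS/mgl sweep before day 7, malT after day 14, malE/sdhC late |
| `freq_dep` | s_h 0.15, c 1.0 | equilibrium s_h/c = 0.15 equals the observed *hfq* peak frequency |

Even at `mu = 1e-9` a population of 1e6 cannot reproduce the experiment's
*counts* (thousands of mutations at >=1%, 7–26 alleles per gene): a 1%
subpopulation of 1.6e10 is 1.6e8 cells, of 1e6 only 1e4, so far fewer
lineages drift or hitchhike into the detectable range. Passing tests show
the machinery is correct under the scaled conditions, not that desk-scale
runs match the published totals; comparisons with the published counts are
therefore structural (classes, spectra shapes, sweep types), never
numerical.

## The sequencing model

Depth per site is Poisson around `mean_depth` (800 by default; a `fixed`
law is available and is what the exact detection formula assumes). Each
read is forward-strand with probability 1/2 and supports the tracked
alternate allele with probability \(f(1-e) + (1-f)e/3\): sequencing errors
are symmetric over the three non-reference bases, so only \(e/3\) of them
hit the one allele being tracked. Library over-dispersion beyond Poisson is
a known simplification — real pooled libraries are noisier, so real
detection probabilities are slightly worse than the model's.

The read-pair generator plants ground truth for the preprocessing stage:
exact byte-identical duplicate pairs (so the first-20-bases key must catch
them) and Q35 segments inside Q2 flanks (so the correct trim span is
known).

## Preprocessing rules

Trimming keeps the longest contiguous segment in which every base has
Phred error probability <= 0.05 (ties leftmost), and discards reads whose
segment is not *longer than* 25 bp — "longer than" is read strictly, so 26
is the minimum kept length; whether the original workflow kept exactly-25
segments is unknowable from the text. PCR duplicates are pairs sharing the
first 20 bases of *both* mates with an earlier pair; first occurrence wins,
order is preserved, mate order matters, and reads shorter than 20 bp use
the whole read as key. This artifact deduplicates before trimming (the
key is defined on untrimmed reads); the original order of the two
operations is not stated and both are exposed as separate functions.

## Variant-calling filters and their exact companion

A site in a sample is called iff (i) it is covered by at least one read on
each strand, (ii) at least 3 reads support the mutant allele, and (iii) the
estimated frequency (mutant reads / total coverage) is >= 1%. "Both
strands" is interpreted as *site coverage* on both strands — the wording
attaches the condition to positions — with a stricter
`alt_on_both_strands` switch provided because the original intent is
ambiguous. Uncalled sites are recorded as frequency 0, never missing:
downstream statistics treat "undetectably low" as zero, as the experiment
did.

Under the fixed-depth error-free model the pass probability is exactly

$$ P(\text{call}) = P\!\left[X \ge \max(3, \lceil 0.01 D \rceil)\right]
   \left(1 - 2\cdot 2^{-D}\right), \quad X \sim \mathrm{Bin}(D, f), $$

because strand labels are independent of mutant status
(`detection_probability()`). At D = 800 the binding constraint is the 1%
rule (8 reads), and f = 1% sits at ~55% detection — the detection limit is
soft, which matters when interpreting singleton counts. Conditional on
passing, frequency estimates near the threshold are biased upward (winner's
curse); the unconditional estimator is unbiased.

## Trajectories and summaries

`build_table()` assembles the mutation x day frequency matrix (0 for
ABSENT). On top of it:

* `occurrence_spectrum()` — histogram of "detected in how many samples";
  bins sum to the number of ever-detected mutations.
* `classify_mutation()` — nested persistence classes: singleton (1 day),
  recurrent (>=2), repeated (>=3), persistent (all days). The experiment's
  text says "greater than three time-points" while its gene table says
  "three or more"; this artifact uses >= 3 and records the discrepancy.
* `mutational_load()` — detected mutations per day split by class.
* `gene_summary()` — per gene with >=1 repeated protein-altering allele:
  samples present, allele count, and peak of the per-day *summed* allele
  frequency (capped at 1). The sum, not the best single allele, is what
  matches phenotypic sweep curves when successive alleles replace each
  other.
* `gene_frequency_sum()` — the genotypic counterpart of a phenotype sweep
  curve; sums above 1 imply same-genome double alleles (or noise) and are
  capped with a warning.

## Cohorts, sweeps, hitchhikers

Linkage is inferred from trajectory concordance. The distance is
L-infinity — linked alleles in one genome must agree in *level* at every
sample day, not merely in shape, which is why correlation is not used.
Clustering is single linkage with threshold `eps = 0.05` (about 3–4
binomial standard deviations at depth 800 for mid-range frequencies),
restricted to mutations whose peak reaches `min_peak = 0.05`; single
linkage is transitive like "same genome" evidence itself, and its chaining
risk is mitigated by the peak floor. Both knobs are exposed. The true
threshold used by eye in the original analysis is unknowable, so `eps` is
validated against simulation truth only.

`classify_gene_sweep()` formalises the verbal criteria: **hard** = exactly
one allele ever >= 0.90 that rose from <= 1% (or from below detection,
i.e. it was absent at an earlier sample) with no other allele ever
established (>= 0.10); **soft** = two or more established alleles;
**incomplete** = a single established allele that does not meet the hard
criteria (this includes a >= 0.90 allele already present at the first
sample — a sweep from standing variation, whose de novo origin cannot be
shown); **none** otherwise. A cohort that contains a driver allele plus
members whose own role is neutral or mutator marks those members as
hitchhikers, the *mutL*/*yggE*/*tpiA* pattern.

## Numerical and degenerate-input choices

* ABSENT = 0.0 keeps trajectories totally ordered; distances well defined.
* Tie-breaks are deterministic everywhere: leftmost longest trim run,
  smallest mutation id in clustering/domination ties.
* `trim_read()` returns 1-based inclusive spans (R convention).
* Zero-coverage sites are never called and carry a `no_coverage` flag.
* A zero-duration run yields an empty trajectory table and empty sweep
  calls rather than an error.
* All randomness flows from one root seed through `derive_seed(root,
  stage)`; re-running a pipeline with the same config and seed reproduces
  byte-identical TSVs (checksummed in the manifest).

## Problem sizes used in the tests

The shipped checks run the simulator at N = 1e4–1e5 with 10–60 day
horizons, 200 replicates for the neutral-martingale band, 50 replicates
for cohort recovery (four planted founder lineages of four linked mutations
each at N = 1e5, depth 800), 100 planted genes per sweep regime for
classifier accuracy, 1e5 Monte-Carlo draws against the exact detection
formula, and 1000 random reads against a brute-force trimming oracle.
These sizes give 3-standard-error statistical bands while keeping a full
run in minutes on one core.

## Known limitations

* Poisson depth (no over-dispersion knob yet) and a single symmetric
  base-error rate.
* Large indels and duplications are abstract records: no breakpoint or
  alignment modelling, and `n_target_sites` is bookkeeping — any
  protein-altering change in a driver gene confers the full role.
* No spatial structure, cross-feeding or consortium dynamics; the model is
  a single well-mixed niche.
* Desk-scale N understates the real mutation supply by ~4 orders of
  magnitude; detected-mutation counts are not comparable to the published
  totals (see the scaling note above).
* Haplotypes are never reconstructed; cohort membership is correlational
  evidence of linkage, exactly as in the original analysis.
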