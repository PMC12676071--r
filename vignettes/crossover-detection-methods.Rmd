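---
title: "Measuring meiotic crossovers in single pollen nuclei: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring meiotic crossovers in single pollen nuclei: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametecross)
```

## The measurement problem

Male meiotic recombination can be measured directly by genotyping individual
haploid pollen nuclei of a diploid plant on a SNP array. Each nucleus is one
meiotic product: a mosaic of the plant's two parental haplotypes, switching
haplotype at every crossover. Three quantities summarise an individual's
recombination behaviour:

* **CC** — crossover count per chromatid (one transmitted chromosome copy);
* **ICD** — inter-crossover distance, in relative chromosome length, between
  successive crossovers on the same chromatid: the observable footprint of
  crossover interference;
* **ICS** — intrachromosomal genetic shuffling,
  $\bar r_{intra} = \sum_{k=1}^{n} 2 p_k (1 - p_k) L_k^2$,
  the probability that two loci drawn uniformly from the genome lie on the
  same chromosome and were uncoupled in that meiosis. Here $p_k$ is the
  proportion of chromosome $k$ inherited from one haplotype and $L_k$ the
  chromosome's share of total genome length.

The pipeline goes from raw gamete genotype matrices to these traits in four
steps: QC, phasing, window aggregation, crossover calling. Every step is a
plain function; `analyze_cohort()` chains them.

## Quality control

Nuclei with an allele call rate below 10% are removed; individuals left with
fewer than three genotyped nuclei are removed; individuals whose set of
nuclei exceeds 50% missing data at the informative markers are removed.
Thresholds are applied as strict inequalities, so boundary cases (call rate
exactly 0.10, missing fraction exactly 0.50) are kept. The call rate is
computed against all assayed markers — QC precedes phasing, and at that
point the informative subset is not yet fixed. The missing fraction is
computed over the concatenated calls of the individual's retained nuclei at
its informative (heterozygous) markers. Both denominators are configurable.

## Phasing by majority voting

Only markers heterozygous in the parent are informative. Because crossovers
are rare relative to marker spacing, consecutive informative markers are
usually co-inherited, so the relative phase of a marker pair is decided by
voting across gametes: a gamete called at both markers votes *cis* (equal
alleles) or *trans* (opposite). The chain of pairwise orientations, anchored
at the first marker of each block, defines the two complementary parental
haplotypes.

Two design points matter:

* **Link window.** With `link_window = 2` (the default) next-nearest marker
  pairs also vote, with weight 1. This is essential, not cosmetic: a single
  miscalled genotype corrupts both adjacent nearest-neighbour votes, and
  with six gametes an unlucky error pattern can flip a consecutive-pairs
  chain with apparent confidence. On simulated parents at default conditions
  (6 gametes, 1% allele-flip error, 5% missing) the consecutive-pairs chain
  phases 95.9% of markers correctly while the two-window chain reaches
  99.2–99.6%. The pure consecutive-pairs chain remains available as
  `link_window = 1`.
* **Ties are never guessed at the marker level.** A zero-margin link splits
  the chromosome into phase blocks. Blocks are then *stitched* at window
  scale: each gamete casts a vote given by its consensus haplotype over up
  to 10 markers on either side of the broken link, and the summed vote
  orients the right-hand block. A genuinely ambiguous link — for instance
  when exactly half the gametes recombined in the interval, which no
  gamete-based method can phase — yields a zero stitch vote and stays
  split. Blocks that remain split and span less than one aggregation
  window are set to missing, so unanchored fragments cannot inject
  spurious haplotype switches. Stitching is what prevents an artifact we
  observed with naive re-anchoring: an arbitrarily oriented second block
  makes *all* of an individual's gametes appear to switch haplotype at the
  same window, producing bursts of phantom crossovers that are highly
  correlated within individuals.

Phasing is identifiable only up to a global haplotype swap per chromosome;
every downstream statistic is invariant to that swap (this is tested).

## Windows, crossover calling, and what cannot be seen

Haplotype-origin tracks are aggregated into ten non-overlapping windows of
10% relative chromosome length (73–96 Mb at the default chromosome sizes)
by majority vote; a window with no called markers or a tied vote is
missing. Crossovers are called as label changes between consecutive
informative windows, positioned at the midpoint of the two flanking window
midpoints. A change whose flanking midpoints are separated by more than 30%
of the chromosome is discarded (`max_gap_rel`); at defaults this admits 0,
1 or 2 intervening missing windows. The 30% bound is inclusive by default
(`gap_inclusive = FALSE` gives the strict reading; both are exposed because
the bound's openness is not decidable from the method description alone).
The number of intervening missing windows is recorded as the event's
*resolution*.

Window-level detection censors real events: double crossovers inside one
window cancel, and crossovers beyond the outermost window midpoints are
invisible. This is a property of the measurement design, not something the
caller tries to repair. The simulator quantifies it — `detectable_events()`
filters the simulated truth by exactly these rules, working from true
haplotype origins without touching genotypes or the calling code path. At
the default distal crossover intensity about a quarter of true events are
censored, and because censoring grows with the crossover rate, a simulated
8% rate reduction is recovered as a slightly attenuated ~7.5% detected
reduction. Group comparisons are unaffected in direction and significance;
absolute detected rates are interpreted as window-scale counts, as in any
gamete-array design.

## Traits and group statistics

Per nucleus, CC is the event count divided by the number of chromosomes;
ICD pools all successive-event distances across the individual's nuclei
before averaging (unweighted by chromosome; individuals without any
multi-crossover chromatid have no ICD); ICS computes $p_k$ from informative
window labels — the unit at which genotypes are defined after aggregation —
with `r_bar_intra()`. ICS is bounded by $\sum_k L_k^2 / 2 \approx 0.072$
for the default karyotype, attained only when every chromosome is an even
haplotype mixture.

Group comparisons use base R's machinery: one-way ANOVA over subpopulation × treatment
cells with Tukey's HSD (`aov()` + `TukeyHSD()`), per-window 2×2 chi-square
tests of event counts against gamete totals with Benjamini–Hochberg
adjustment across windows, Pearson correlation for landscape profiles, and
Spearman rank correlation for beneficial-allele stacking. cM/Mb conversion
treats each event as contributing $100 / n_{gametes}$ cM, i.e. the
frequency of recombinant chromatids times 100.

## The simulator

`simulate_cohort()` generates the full data-generating process the analysis
assumes, with complete ground truth:

* **Crossover placement.** A stationary gamma renewal process along the
  chromosome with mean rate `lambda_cc` (default 2.2 per chromatid) and
  shape `interference_nu` (default 5). Shape 1 is a Poisson process —
  no interference; larger shapes under-disperse counts and widen
  inter-crossover distances, which is how interference manifests in the
  data. Stationarity is achieved by burn-in, so the marginal event rate is
  exact. Positional intensity defaults to a distal-skewed profile
  $f(x) \propto 0.4 + 1.8\,(2x-1)^2$ (terminal/pericentromeric ratio 5.5),
  the broad-scale shape of large cereal chromosomes whose pericentromeric
  recombination is suppressed; `"uniform"` is available and is used in the
  flat-landscape calibration test. The renewal process runs on the
  intensity-transformed scale, so interference operates in "event space"
  and the marginal position density follows the profile.
* **Markers and genotypes.** 400 uniformly placed markers per chromosome
  with heterozygosity 0.5 give ~200 informative markers per chromosome
  (~1400 genome-wide, ~20 per window). Window-level analysis is insensitive
  to density beyond ~10 markers per window, so this emulates a several-
  thousand-SNP array at a fraction of the cost; the array itself (the
  marker map) is drawn once per cohort and can be shared across cohorts via
  the `map` argument — as in a real study where all samples run on one
  array. Genotyping noise is a symmetric allele flip (1%) plus missing
  calls (5%); haploid data contain no heterozygous calls. An optional
  `bad_nucleus_rate` produces failed amplifications (>90% missing) for QC
  testing.
* **Cohort structure.** Two subpopulations × two treatments; nutrient
  deficiency multiplies the crossover rate by $1 - \delta$ (default
  $\delta = 0.08$); an optional `subpop_effect` raises the second
  subpopulation's baseline. Within-individual variance beyond the renewal
  process itself is not modelled — no data were available to calibrate a
  between-nucleus variance component, and the renewal counts already
  reproduce the observed nucleus-level spread.

What the simulator does **not** emulate: real marker ascertainment and
clustering (its markers are uniform, so missing windows are rarer than on a
real array and nearly all events have resolution 0), segregation-distorting
postmeiotic selection, gene conversion (invisible at this window size
anyway), and linkage disequilibrium between individuals' haplotypes.
Passing tests therefore demonstrate correctness of the inference given the
assumed generative model, not robustness to every artefact of a particular
array.

## Validation design

The test suite validates the pipeline against ground truth in five ways,
at the default cohort conditions (6 nuclei, $\lambda = 2.2$, $\nu = 5$, 5%
missing, 1% error):

1. **Exact oracle.** At zero noise, called events must equal
   `detectable_events()` truth *exactly* — positions, resolutions, per
   nucleus — on chromosomes whose phase is identifiable. Identifiability
   fails for a small fraction (3–7% of chromosomes in 100-individual runs):
   marker intervals where half or more of the six gametes recombined are
   unphaseable or actively misleading for any majority scheme, and residual
   block splits censor short terminal fragments. These chromosomes are
   excluded from the exact comparison and their fraction is itself bounded
   in the test; unconditional exactness at six gametes is not attainable by
   any method.
2. **ICS oracle.** The closed-form $\bar r_{intra}$ must match a
   Monte-Carlo two-locus experiment (a million uniformly drawn genome
   position pairs per gamete) within 0.01.
3. **Parameter recovery.** Across 100 seeded cohorts of 250 individuals
   per treatment group, Tukey's HSD must detect the simulated 8% reduction
   at $\alpha = 0.01$ in at least 80 seeds, and the mean estimated relative
   reduction must hold −8% within its 95% sampling band.
4. **Phasing accuracy.** At least 99% of markers phased consistently with
   truth (up to per-chromosome flip) over 50 simulated parents.
5. **Null calibration.** Two cohorts from the same generator (sharing one
   marker map) must show no BH-significant per-window differences in at
   least 95 of 100 seeds.

Numerical conventions worth stating: relative positions live in $[0, 1]$
with half-open windows (the last closed); event positions sit exactly on
window-midpoint boundaries, so window assignment nudges by $10^{-9}$ before
flooring to avoid floating-point truncation; bp positions are 1-based; all
randomness descends from a single integer seed and cohort generation is
byte-identical across runs.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 40, seed = 7)
bundle <- simulate_cohort(cfg)
res <- analyze_cohort(bundle)
head(res$traits)
ge <- group_effects(res$traits, "cc_per_chromatid", factors = "treatment")
ge$contrasts
ls_all <- build_landscape(res$events, nrow(res$nuclei), res$map)
attr(ls_all, "genome_rate_cm_per_mb")
```

The `analysis/` directory holds the cohort-scale workflow: simulation at
reference-cohort scale (584 individuals), QC + phasing + calling, group comparisons,
landscape contrasts, and allele stacking, each writing its tables under
`results/`.

## Known limitations

* No real array dataset is bundled; the IO layer reads the standard
  delimited export format (samples × markers, A/B calls, plus a marker map
  and metadata), so the workflow applies directly to locally available
  array data. Cohort-level numbers for a real population can of course
  only be computed from such files.
* ICD is bounded below by one window width (0.10), so interference
  estimates are coarse; the window design trades positional resolution for
  robustness at three to six gametes per individual.
* The per-window chi-square contingency (events vs non-events per gamete)
  is one of several defensible constructions; it is the package's
  documented choice and is exposed in `compare_landscapes()`.
* When cohorts differ in subpopulation composition as well as treatment,
  pooled landscape comparisons mix both effects; comparisons can be run
  within subpopulation by subsetting the event table.
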