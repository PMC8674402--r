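---
title: "Dissecting seed low-temperature germinability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting seed low-temperature germinability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltgmap)
```

## The problem

Low-temperature germinability (LTG) — the capacity of rice seed to
germinate at chilling temperature (around 15 °C) — is a quantitative
trait of direct agronomic value for direct-seeded and high-latitude
rice.  `ltgmap` implements a complete genetic-dissection workflow for
such a trait around four experimental designs:

1. a **single segment substitution line (SSSL) library**, where each
   line carries one homozygous marker-defined donor segment in an
   otherwise uniform recurrent-parent background, scanned season by
   season for phenotypic deviation from the recurrent parent;
2. **substitution mapping**, which localizes a locus by intersecting the
   substituted segments of lines that show the phenotype and subtracting
   the segments of overlapping lines that do not;
3. an **F2 validation population** with segregation tests, coded
   single-marker regression for additive/dominance effects, and
   recombinant-progeny fine mapping in physical coordinates;
4. **bulked-segregant sequencing (QTL-seq)**: ΔSNP-index profiles from
   two phenotypic-extreme bulks, compared against simulated null
   confidence bands; and a **candidate-gene filter cascade** over the
   fine-mapped region.

A forward simulator generates all of these data types with known ground
truth, so every stage has a no-download test surface.

## SSSL scanning

Germination proportions are variance-stabilized with
$\theta = \arcsin\sqrt{p}$ (radians) before any test; two-sided
*pooled-variance* Student's t tests compare each line with the
recurrent parent within a season.  We use the pooled-variance form
because that is what the test's name denotes in this literature; Welch
would differ negligibly at these replicate numbers.  A putative QTL is
declared when $p < \alpha$ (default $10^{-3}$) in at least
`min_seasons` (default 2) cropping seasons.  No multiple-testing
correction is applied: the two-season replication requirement *is* the
false-positive control (the acceptance suite verifies an empirical
false-positive rate below 0.5 % under the null generator).

Effects are computed on the **raw proportion scale**: with one
substituted segment homozygous in the line, the additive effect is
$a = (\bar y_{\text{line}} - \bar y_{\text{parent}})/2$ and the
contribution is $R^2 = a / \bar y_{\text{parent}}$.  The transform is
for testing only; published per-line effect tables are reproducible only
on the raw scale (an effect of $a \approx 0.16$ against a parent mean
of $\approx 0.54$ gives the printed $R^2 \approx 30\,\%$).  Per
detected season, effects are averaged with their sample SD ($n-1$).
The replicate unit is the plant (a plant's two dishes are averaged
upstream); this is configurable by how the replicate vectors are built.

**Heritability.**  The estimator is not pinned down by the published
description, so we chose: per season, a one-way random-effects
method-of-moments partition with
$H^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_e)$ (unbalanced designs use
the standard $n_0$ coefficient); across seasons, a two-way partition
with line, season and line-by-season strata and
$H^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_{G\times E} + \sigma^2_e)$.
Negative moment estimates are truncated at zero, which keeps
$H^2 \in [0,1]$.  Published $H^2$ values are *not* used as numeric
targets: they depend on unpublished per-line raw data.

## Substitution mapping and the interval engine

Substituted segments are described by two nested closed cM intervals:
the **core** (between the inner marker pair, certainly substituted) and
the **maximal** interval (out to the outer flanking markers, where
recombination may have placed the true boundary).

Grouping and localization use one interval algebra, whose three
conventions matter and were genuinely open design choices:

* **Overlap requires positive length.**  Two lines whose maximal
  intervals merely touch at a single shared marker share no interval of
  genetic material; treating them as overlapping would fuse loci that
  the data keep separate (two adjacent same-sign loci on one chromosome
  can share a flanking marker).
* **Intersection is closed**, and may legitimately be a single point.
* **Negative evidence subtracts open interiors.**  A line in which the
  QTL was *not* detected excludes the interior of its core segment, but
  a boundary marker shared with the remaining interval stays in: a QTL
  at the boundary marker itself cannot be excluded by either line.

Groups are connected components of the overlap graph restricted to one
chromosome and one effect sign (overlapping detections of opposite sign
are distinct loci).  Names follow the rice convention
`q<TRAIT><chr><letter>`, lettering short-arm to long-arm only when a
chromosome carries several loci.  A locus interval is the intersection
of member maximal intervals minus the cores of overlapping
non-significant lines; an empty intersection among members is an error,
while negative evidence that excludes everything is returned as an
empty, conflict-flagged result — both are conflicts a user must see,
not silently drop.

The engine is verified against a brute-force oracle: discretize the
chromosome at 0.1 cM, mark each grid point as candidate iff it lies in
every member maximal interval and not strictly inside any negative
core, and require the engine's intervals to reproduce that membership
exactly (1000 random cases in the acceptance suite).  The same engine,
run in base pairs, performs recombinant fine mapping: heterozygous
intervals of progeny populations with a significant marker-trait
association (default $p < 0.01$, the level used for progeny tests in
this design) are intersected; non-significant ones are subtracted.

**Map fixture.**  Published SSSL tables give marker orders and segment
lengths but no cM coordinates, so the packaged map lays out positions
consistent with the printed lengths and localized intervals; the four
non-significant overlapping lines carry synthetic marker names.  The
packaged recombinant fixture likewise uses synthetic bp coordinates
that realize the published 332.7-kb flanked span.  Interval *lengths*
are therefore fixture properties; the engine's correctness is anchored
to the grid oracle, and only fixture-stable quantities (group count,
member sets, averaged effects) are treated as reproductions.

## F2 genetics

Genotypes are coded 1/2/3 (recipient homozygote, heterozygote, donor
homozygote).  Segregation is tested with the plain Pearson χ² against
1:2:1 (no continuity correction).  Effects come from ordinary least
squares on the standard dummy coding
$y = \mu + a x + d z + \varepsilon$ with $x \in \{-1, 0, 1\}$ and
$z \in \{0, 1, 0\}$; because the model is saturated on three genotype
classes, $\hat a = (\bar y_3 - \bar y_1)/2$ and
$\hat d = \bar y_2 - (\bar y_1 + \bar y_3)/2$ exactly, for any class
sizes.  Designs with a single class are errors; with two classes the
missing contrast is flagged inestimable.  Missing genotypes are
dropped listwise and reported.  Marker–trait association is the
Pearson correlation of code against phenotype with its two-sided test.

## ΔSNP-index analysis

With "alt" oriented to the donor allele (sites where the two parents
are not opposite homozygotes are dropped when reading a VCF), the
SNP-index of a bulk is $\mathrm{alt}/(\mathrm{ref}+\mathrm{alt})$ and
Δ is tolerant-bulk minus sensitive-bulk index.  Default site filters
follow common QTL-seq practice (the source protocol is silent): total
depth ≥ 10 in each pool, and sites with index < 0.3 in *both* pools
dropped as likely alignment artefacts; both configurable.

"Fitting" along the chromosome is a sliding-window arithmetic mean
(default window 1 Mb, step 100 kb) — the smoother is unspecified in the
protocol this reimplements, and a windowed mean keeps the null band
construction exact rather than approximating loess weights.

The null band is Monte-Carlo: under no linkage each bulk's allele
frequency is $\mathrm{Bin}(2m, 0.5)/(2m)$ for a bulk of $m$ F2 plants
(selfing cross, expected frequency 0.5), read counts are binomial at
the site's observed depth, and the per-site two-sided empirical
quantiles are then window-averaged exactly like Δ itself.  One seed
governs all draws; identical seeds give identical bands.  Note a
calibration subtlety: the band is a *per-site* quantile averaged over
the window, so when a window averages $k>1$ sites the smoothed Δ has
smaller variance than the band assumes and exceedance is conservative.
The 5 % ± 1.5 % coverage check in the acceptance suite therefore uses
one site per window, which is the configuration in which the nominal
level is exact; with the default 1 Mb/100 kb smoothing the band errs on
the safe side.  Candidate intervals are maximal runs of consecutive
windows exceeding the band on one side (opposite-sign runs are never
merged; empty windows break a run).

## The synthetic world

The generator's defaults state the emulated design rather than tune any
test: four cropping seasons with recurrent-parent germination means
67.7, 57.4, 55.3 and 44.1 %; 4 replicate plants per line and season
(the design harvested 3–5) with 150 seeds per plant (dishes held
100–200); plant-level residual SD 0.03 and line-by-season shift SD
0.02 on the proportion scale — values that put single-replicate SDs in
the low percent range typical of germination assays; donor segments
uniform on 5–40 cM (the real library spans 0.4–70 cM, mean 15.8); an
F2 of 356 plants with genotype means 52/65/78 % ($a = 0.13$, $d = 0$,
residual SD 0.10); 30-plant extreme bulks sequenced at mean depth 30.
Phenotypic effects are additive on the proportion scale with clipping
to [0.01, 0.99] before binomial seed sampling, mirroring how $a$ and
$R^2$ are defined on raw germination percentages.  Recombination uses
the Haldane map function; interference is out of scope.  Bulks are
selected by phenotype rank with ties broken by individual id.

What a green simulation test establishes: the pipeline recovers planted
effects (MAE ≤ 0.02), localizes planted loci, and controls false
positives *under this generative model*.  What it does not establish:
robustness to sequencing error, alignment bias, segregation distortion,
epistasis between segments, or non-additive scale effects — none of
which the generator emulates.

## Numerical conventions

* Report rounding is half-away-from-zero (2 decimals for $a$, 1 for
  percent), required to reproduce published row values such as a
  30.95 % mean printed as 31.0.
* Intervals are closed; degenerate (zero-length) pieces are preserved
  by the engine so that the grid oracle equivalence is exact.
* Proportions are validated into [0, 1] at construction; zero-depth
  sites become missing and are excluded before smoothing.
* All simulators are pure functions of `(config, seed)`.

## Known limitations

* The candidate-gene cascade's "hypothetical" rule is clause-based text
  matching; exotic annotation phrasings outside the packaged vocabulary
  would need the pattern extended.
* The one-QTL-per-SSSL assumption is adopted verbatim; two linked
  planted QTLs inside one segment are summed into a single apparent
  effect.
* Interval calling reports windowed spans, so boundary resolution is
  one window step.
* The combined-heritability estimator assumes near-balanced
  line-by-season replication; severely unbalanced data get a
  mean-cell-count approximation.
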