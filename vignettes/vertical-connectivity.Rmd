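---
title: "Vertical connectivity of total and active communities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vertical connectivity of total and active communities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertconn)
```

`vertconn` analyses paired 16S rDNA (total) and 16S rRNA (active) amplicon
count tables collected along a stratified water column. This vignette is
the package's account of the underlying models: what each step assumes,
which parameters matter and why their defaults were chosen, the numerical
conventions used for edge cases, what the synthetic generator does and does
not emulate, and the limitations a user should keep in mind.

## The data model

The unit of observation is a (station, depth) water sample sequenced twice:
once from the 16S rRNA **gene** pool (every cell regardless of state) and
once from the 16S rRNA **transcript** pool (cells with recent potential for
protein synthesis, called *active* throughout — a deliberate shorthand, see
Limitations). Both pools are tabulated over the same amplicon sequence
variants (ASVs). `pair_tables()` aligns the two tables onto the sorted
union of their ASV axes, zero-filling where a pool lacks an ASV, so that
every downstream comparison is cell-by-cell.

Sample metadata attach a station, a depth in metres, a per-station depth
index d1 (surface) … d7 (bathypelagic, ~2600–4000 m), and one of five
analysis layers (surface, DCM, upper mesopelagic, lower mesopelagic,
bathypelagic). Depth indices are positional per station: a station missing
an intermediate depth keeps its native indices, and no interpolation is
attempted. Missing metadata for a sample is an error rather than a
warning, because every analysis keys on the depth index.

Counts are stored as reals: copy-number correction and rarefaction
averaging both produce non-integer tables. Operations defined on raw reads
(rarefaction) validate integrality themselves, which makes the intended
pipeline order explicit instead of silently coercing.

## Preprocessing

**Repeated rarefaction.** Detection-based quantities (richness, first
depth of detection, fates) are extremely sensitive to library size, so all
of them are computed on tables rarefied to a common depth: each sample is
subsampled without replacement to 10 000 reads, 100 times, and the
per-cell mean is used (`rarefy_repeated()`, built on `vegan::rrarefy`).
Averaging stabilises the presence pattern of rare taxa: an ASV is treated
as detected when its mean is positive, i.e. when it appeared in at least
one of the 100 subsamples — the most inclusive deterministic rule, chosen
because any stricter cutoff would need an arbitrary threshold. Samples
below the rarefaction depth are excluded (with a warning naming them), not
rarefied to the minimum: a shrinking common depth would silently change
every detection probability. One seed fixes all 100 subsamples. Samples
already at the target depth pass through unchanged, since subsampling
N reads from N is the identity.

Note that diversity indices are computed once on the averaged table rather
than averaged over per-permutation indices. At a depth of 10⁴ reads the
two differ by far less than between-sample variation (Jensen-gap terms of
order 1/depth), and the averaged table keeps a single detection notion for
the whole pipeline.

**Copy-number correction.** 16S operon copy numbers vary roughly 1–15×
across taxa, so read fractions overstate multi-copy taxa. Where a
copy-number lookup is available, `correct_copy_number()` divides each ASV
by the mean copy number of its deepest assigned rank among order, family
and genus; ASVs resolved only to class or above are left unchanged,
because predictions that coarse add more bias than they remove. Per-sample
totals are rescaled back to the originals, making the correction a
redistribution of reads. The correction is applied to *contribution*
analyses (who carries which fraction of the community) and never to
diversity indices — dividing a presence/absence-driven index by copy
number has no meaning. Because corrected counts are non-integer,
correction necessarily follows rarefaction.

**CLR transform.** Compositional analyses use the centred log-ratio
clr(x)ᵢ = ln(xᵢ + c) − mean ln(x + c). Zeros are handled with a
pseudocount c = 1 on every cell — the same convention as the activity
ratios, so the two analyses share one zero model; c is configurable, and
c = 0 is allowed for strictly positive tables (where CLR becomes exactly
scale-invariant). Beta-diversity (NMDS, PERMANOVA, dispersion) operates on
the *non-rarefied* tables: Aitchison geometry is scale-free, so
subsampling would only discard reads.

## Diversity and group tests

Richness is the count of detected ASVs; Shannon H is in nats so that
Pielou's J = H/ln(nASV) lies in [0, 1] (J is reported missing for
single-ASV samples rather than 0/0). Faith's PD is the sum of branch
lengths of the minimal subtree connecting a sample's ASVs *and the root*
(`picante::pd`, `include.root = TRUE`); the rooted convention keeps
single-taxon samples well-defined and makes PD monotone under taxon
addition, and an unrooted variant is available. PD/richness measures the
phylogenetic breadth per taxon: active communities can be less rich yet
more phylogenetically dispersed, and this ratio is how that contrast is
quantified.

DNA-vs-RNA contrasts use two-sided Mann–Whitney tests (exact by
enumeration when both groups have ≤ 8 values and no ties; otherwise the
tie-corrected normal approximation), because per-layer diversity values
are few and not plausibly normal. Comparisons across the five depth layers
use Kruskal–Wallis with Dunn's rank-based z post hoc comparisons; Dunn p
values are unadjusted by default (adjustment is the caller's choice via
`p.adjust` methods, since conventions differ across fields).

## Community structure

`permanova()` runs a one-factor PERMANOVA on the Aitchison distance
matrix: pseudo-F from the partition of squared distances (SS_total =
Σd²/n, within-group SS from within-group squared distances divided by
group sizes), p = (#permuted F ≥ observed + 1)/(n_perm + 1) with 1000 free
permutations by default. No restricted permutation strata are used — the
design treats samples as exchangeable under the null. The combined
DNA + RNA analysis (`permanova_pooled()`) stacks both CLR tables and runs
*two one-factor tests* (depth layer; molecule) on the pooled matrix rather
than a crossed two-factor model, matching the reporting convention of one
grouping variable per row.

NMDS (`nmds()`) minimises Kruskal stress-1 by monotone regression with 20
random starts, 300 iterations and stress tolerance 1e-7 (all configurable;
the values are standard practice, not sacred). Within-layer dispersion is
reported descriptively as the multiset of within-layer pairwise distances
against the grand mean pairwise distance — the box-plot contrast — rather
than through a formal dispersion test.

## Activity ratios

Per-ASV activity is summarised as log₂((RNA + 1)/(DNA + 1)) on rarefied
mean tables, so both pools share the 10 000-read scale and the pseudocount
means the same thing in each; the pseudocount keeps ratios finite for taxa
inactive (RNA = 0) or DNA-undetected in a sample. Group-level ratios
aggregate member reads *before* the ratio, and groups are only reported
when their data-set-wide DNA total exceeds 500 reads — a global filter, not
per-sample, so a group does not flicker in and out across samples. Mixed
taxonomic resolution (phylum by default, Proteobacteria at class,
alpha/gamma classes at order) is expressed as a recursive refinement map
(`assign_reporting_groups()`), with the most specific applicable rule
winning.

## Vertical connectivity, shifters, fate and rarity

**First-detection categories.** Per station, every ASV is assigned the
first depth index at which it is DNA-detected, assuming surface-to-deep
directionality (sinking particles being the dominant dispersal vector
down the water column). Detection is based on the DNA pool only; an ASV
RNA-detected but never DNA-detected at a station is a *phantom* — too rare
for the gene survey but active enough to appear among transcripts — and is
a category of its own rather than inheriting a depth. Stations are
processed independently, so the same ASV may be d1 at one station and d3
at another. A station without a surface sample is an error: directionality
is undefined there. Category contributions are read fractions by default
(ASV-count fractions are available), and over {d1…d7, phantom} they sum
to 1 per sample and pool; the DNA pool's phantom fraction is structurally
zero.

**Shifters.** To find the taxa whose transcript abundance changes most,
each ASV gets the mean over all unordered sample pairs of |RNAᵢ − RNAⱼ| on
the rarefied scale (the one-dimensional Euclidean distance between
samples), computed over all stations pooled. ASVs with mean change > 10
reads are *shifters*; the threshold is meaningful only on the 10 000-read
scale. A shifter is *sunlit* when its mean RNA abundance across surface
samples exceeds its mean across bathypelagic samples, *deep* in the
opposite case; exact ties stay unclassified with a warning. The per-sample
profiles of the surface-categorised (d1) shifters report raw summed RNA
contributions and mean log₂ ratios — any curve smoothing is left to
plotting, since it is presentation, not analysis.

**Fate.** At each station's d7 sample, the station's d1-category ASVs are
partitioned into *active* (DNA- and RNA-detected), *inactive* (DNA only)
and *lost* (DNA-undetected). The three classes partition the station's
surface-derived richness by construction, and the package asserts this.

**Rarity and occurrence.** Surface-detected ASVs are classed by their
maximum relative abundance across surface DNA samples — abundant (> 1 %),
rare (0.1 % < x ≤ 1 %), very rare (≤ 0.1 %) — and by the fraction of
stations whose surface sample detects them — ubiquitous (> 70 %),
intermediate (30–70 %), local (< 30 %). Verbal definitions of such classes
are usually open/closed-inconsistent; the half-open conventions above make
the classes exhaustive and mutually exclusive, the boundaries are pinned
by tests at exactly 1 %, 0.1 %, 30 % and 70 %, and all four cutpoints are
configurable. "At least one sample" makes the abundance class global: an
ASV abundant at a single station is abundant, full stop.
`bathy_active_rarity_breakdown()` then splits the surface-derived active
bathypelagic RNA mass by these classes and, for the taxa that become
abundant (> 1 % RNA) in the bathypelagic active pool, counts the depth
indices at which each is DNA-detected (water-column cosmopolitanism).

## The synthetic generator

`simulate_survey()` is not a fixture factory but a first-class module: it
generates paired count tables whose every downstream statistic has a known
planted value, which is how the pipeline is validated end to end.

The model: each ASV carries a per-depth *expected read weight* for DNA and
for RNA on a 10 000-read scale, plus a station presence mask. Counts for a
sample are one multinomial draw per pool with the sample's library size
(uniform on 10 000–12 000 by default, so rarefaction is a genuine
subsample) over the masked weights. The RNA weight divided by the DNA
weight is the per-depth activity multiplier; parameterising by RNA weights
directly makes the planted fractions exact. Multinomial (rather than
Dirichlet-multinomial) sampling keeps recovery tolerances analytic.

The default scenario encodes the reference study conditions: 13 stations ×
7 depths (3, 106, 430, 700, 970, 2000, 4000 m), ~5000 ASVs — 1040 surface
origin split into abundant (20 taxa, 150–250 expected surface reads), rare
(120; 15–60) and very rare (900; 2–4); 3740 deeper-origin taxa; 200
RNA-only phantoms. Planted structure, all recoverable by the pipeline:

* surface-derived taxa carry **50 %** of the expected bathypelagic RNA
  reads, split 30/45/25 across abundant/rare/very-rare surface classes
  (so rare + very rare = **70 %** of the surface-derived active bottom
  pool) — the d7 blocks are rescaled exactly to these shares;
* the expected per-station fraction of detected surface taxa still
  DNA-detected at d7 is **15 %**; the survivor count is solved from the
  occurrence mix so this holds per station, and non-survivors decay with
  depth following a fixed maximum-depth distribution;
* **25 sunlit** shifters (150 expected RNA reads at the surface, 0 below
  the DCM) and **25 deep** shifters (~5 reads shallow, 110–190 at d7),
  both with a ≥ 100-read surface-vs-deep contrast;
* occurrence classes (60 % ubiquitous, 25 % intermediate at 6/13 stations,
  15 % local at 2/13) planted on the surface taxa that never reach the
  bottom. Bottom-reaching taxa are kept ubiquitous so the planted bottom
  fractions hold exactly at every station — a deliberate simplification;
  real surveys also contain patchy survivors.

A design constraint worth spelling out: the shifter statistic responds to
sampling noise alone. For an ASV with a flat expected abundance μ across
all samples, Poisson-scale noise gives a mean pairwise change of about
1.13 √μ, which crosses the detection threshold of 10 near μ ≈ 80 reads;
taxa present in only a subset of samples cross it even earlier (a taxon at
v reads in the 26 shallow samples and absent below contributes
≈ 0.41 v). All *background* RNA expectations are therefore capped at 15
reads, constant-profile active survivors sit at ~30, and only the planted
shifters exceed the threshold — so planted precision/recall are meaningful.
Consequently the generator cannot represent communities whose background
taxa are both abundant and strongly depth-varying in RNA without those
taxa being, correctly, shifters.

`expected_fractions()` recomputes the planted expectations (category read
fractions per station/depth/pool, per-station survival) in closed form
from the weights, without sampling: this is the oracle the recovery tests
compare against. Degenerate switches exercise analytic limits: RNA ≡ DNA
weights (ratios → 0 as libraries grow), zero survival (every surface
taxon lost at d7), and depth-homogenised RNA (within-layer RNA dispersion
falls below DNA dispersion in the bathypelagic).

What the generator does **not** emulate: taxon–taxon correlations and
overdispersion beyond multinomial noise, chimeric/denoising artefacts,
copy-number structure confounded with abundance (copy numbers are drawn
independently), station-level environmental gradients within a depth, or
sequence-level evolution (the phylogeny is a random rooted tree with
exponential branch lengths, used to exercise PD code paths, not to mimic
marine phylogenetic structure). Passing recovery tests therefore show the
*pipeline* is correct under the stated sampling model — they are not
evidence about any real data set.

## Numerical conventions and edge cases

* Detection is strictly `> 0` everywhere; all class boundaries are pinned
  by tests at their exact cutpoints.
* Rarefied tables sum to the depth within 1e-6 × depth; CLR rows sum to 0
  within 1e-9 × nASV; category fractions sum to 1 within 1e-9.
* Pielou's J for a single-ASV sample, and the active proportion of a
  sample with zero DNA detections, are missing values with warnings, not
  zeros.
* Mean pairwise change is computed from sorted abundances via
  Σᵢ (2i − n − 1) x₍ᵢ₎ / C(n, 2) — O(n log n) per ASV and exactly equal to
  pair enumeration.
* The exact Mann–Whitney branch is used only for ≤ 8 + ≤ 8 untied values;
  identical-value degenerate inputs return p = 1 with a warning.
* PERMANOVA p values are reproducible under a fixed seed, bounded below by
  1/(n_perm + 1); with few samples the permutation engine may enumerate
  the complete set, which only sharpens the p value.
* All simulation, rarefaction and permutation randomness is controlled by
  explicit integer seeds.

Problem sizes used by the test-suite and the acceptance script — the full
13-station scenario with 100-fold rarefaction for final recovery, a
4-station variant of the same ASV pool for module tests, 500-replicate
null calibrations at 99 permutations, and 200 random subsets for the PD
oracle — were chosen so the whole validation runs comfortably on a laptop
while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* "Active" means ribosome-bearing: rRNA content is an imperfect proxy for
  growth (dormant cells can retain ribosomes; translation efficiency
  varies across taxa), so ratios and active fractions should be read as
  potential for protein synthesis, not measured activity.
* First-detection categorisation inherits its directionality assumption:
  taxa dispersed upward or horizontally are misattributed to the depth
  where they first appear.
* The shifter threshold (10 reads mean change) is tied to the 10 000-read
  rarefied scale; on other scales it must be rescaled by the user.
* Per-station categorisation makes results sensitive to single-sample
  detection noise for taxa near the detection limit; the generator's
  recovery analysis quantifies this (it is the dominant error term for
  very rare taxa).
* PERMANOVA with free permutations tests location and dispersion jointly;
  a significant result does not separate the two (dispersion is reported
  descriptively for that reason).
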