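---
title: "Screening for functionally convergent lncRNAs: models, parameters, and design choices"
author: "lncanalog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for functionally convergent lncRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Long noncoding RNAs evolve quickly at the primary-sequence level, so
orthology searches based on alignment routinely fail across distant
vertebrates. Yet functionally equivalent lncRNAs can exist in species where
no alignable counterpart is detectable: transcripts of independent genomic
origin that converged on a similar *composition* of short sequence motifs
and a similar secondary structure. `lncanalog` implements a screen for such
functionally convergent ("analogous") lncRNA pairs. A candidate analog of a
query lncRNA must pass four gates:

1. **k-mer content** — high background-standardized k-mer correlation with
   the query, in the top percentiles of the target set at *every* k
   (default k = 3..6, 99th percentile), plus a reciprocal screen in the
   opposite direction (default 96th percentile);
2. **noncoding status** — an ORF/Fickett coding-potential filter;
3. **secondary structure** — a normalized structural distance below 0.095
   between the query's structure profile and its best-matching sub-region
   of the candidate, with an empirical p-value from dinucleotide-shuffled
   nulls;
4. **absence of linear homology** — no sliding-window conserved segment
   (70% identity over 100-bp windows) and, optionally, dotplot inspection.

The conjunction matters: the screen looks for *nonlinear* similarity, so a
hit must resemble the query in composition and structure while *failing*
conventional alignment.

## k-mer similarity

Every transcript is summarized by its vector of overlapping k-mer counts
normalized to counts per kilobase (denominator: full sequence length /
1000; windows containing `N` are skipped). Counts are z-scored against a
background population — in a real screen, the complete lncRNA annotation of
the query species — using the per-k-mer mean and *population* SD across the
background. The similarity of two transcripts at one k is the Pearson
correlation of their standardized vectors; a screen ranks a query's
correlation to each target as an inclusive percentile (`100 * #{r_t <= r} /
n_targets`) so that the best target sits at exactly the 100th percentile.

Two conventions are deliberate and recorded rather than silently assumed:

* **Optional `log2(x + 1)` transform** before standardization. Published
  k-mer screens differ on this; the flag defaults to off and is stored in
  the background model and in run provenance, so either convention is
  reproducible.
* **Inclusive percentile with the candidate in its own population.** This
  makes a printed "100th percentile" attainable, which is how headline
  values of this kind of screen are reported.

k-mers with zero background SD are standardized to 0 (not dropped) so all
vectors keep length 4^k and remain comparable across queries.

## Coding-potential filter

The screen only admits noncoding candidates. Web-service classifiers are
not reproducible offline, so the package uses a transparent stand-in with
two published, auditable features: the longest complete forward-strand ORF
(ATG to in-frame stop; coding if >= 300 nt) and the Fickett TESTCODE
statistic from the original lookup tables (coding if >= 0.95). Both
thresholds are parameters and are echoed in every call. This filter plays a
binary gating role in the screen; it is not a reimplementation of any
specific web service's SVM.

## Structure comparison

Structure profiles are per-nucleotide scores whose sign distinguishes
double-stranded (> 0) from single-stranded (< 0) propensity. The default
backend runs ViennaRNA's `RNAplfold -u 1` and reports `P(paired) - 0.5`,
i.e. an equilibrium pairing propensity centered at probability 0.5. Any
per-nucleotide profile source can be plugged in instead — either an R
function or TSV files of precomputed scores — and the backend tag is
recorded in results. Profiles from a trained structure predictor will give
different absolute distances than the thermodynamic backend; distances are
comparable only within one backend.

Profile comparison uses dynamic time warping with steps
{(1,0), (0,1), (1,1)} and local cost `|p_i - q_j|`. The reported distance
is **accumulated cost divided by path length**, minimized *as a ratio* over
all warping paths. This choice makes the open-begin-end (OBE) variant —
where the path may start and end anywhere along the longer profile —
exactly equal to the minimum of the anchored distance over all sub-intervals
of the long profile, a property the test suite checks against exhaustive
enumeration. The ratio minimization is solved exactly by Dinkelbach
iteration: each step is one ordinary DTW pass with per-cell cost
`|p_i - q_j| - lambda`, and lambda is updated to the ratio of the argmin
path until convergence (a handful of passes; fractional programming over a
finite path set terminates at the global optimum). Ties in the DP are broken
deterministically (diagonal, vertical, horizontal; smallest end column).

Significance is assessed against dinucleotide-preserving shuffles of the
*longer* sequence: the Altschul-Erikson Eulerian-path construction keeps
the exact multiset of overlapping dinucleotides (hence length, endpoints,
mono-nucleotide composition and GC), the profile is recomputed and the OBE
search rerun for each shuffle, and `p = (1 + #{d_null <= d_obs}) / (1 + n)`.
The default `n_shuffles = 1000` gives a p-value floor of 0.001; tests and
quick runs use 19-99. A pair is called structurally similar when the
normalized distance is below 0.095, the conventional cutoff below which RNA
structure profiles are considered equivalent (0.095-0.10 or higher:
different).

## Linear-homology exclusion

The screen's final gate demonstrates the *absence* of conventional
similarity. Two instruments are provided:

* **Dotplot** with the classic DNA settings (window 5, threshold 25,
  match +5, mismatch -4), under which a hit is exactly a shared 5-mer;
* **Sliding-window identity** over a global alignment: windows of 100
  reference bases at 25-base steps, identity = matching columns / window
  size with reference-to-gap columns counted as mismatches; conserved
  segments are maximal runs of full windows at >= 70% identity. An empty
  segment list is the expected outcome for convergent pairs.

The global aligner is `Biostrings::pairwiseAlignment` with affine gaps. Its
default gap parameters here are deliberately stiff (open -16, extend -4
against match +1 / mismatch -1): opening a gap must buy roughly ten extra
matches. The choice is load-bearing. With permissive gap costs, the optimal
global alignment of a 600-nt sequence against an *unrelated* 3600-nt
sequence reaches 76-89% window identity — the sixfold length surplus lets
the optimizer cherry-pick matches (a longest-common-subsequence effect) and
a "conservation" plot of random sequences would cross the 70% threshold.
Anchor-based genomic aligners, whose role this module fills, align only
significantly matching blocks and show background identity elsewhere; the
stiff penalties reproduce that behavior (unrelated 600 vs 3600 nt pairs
stay near 51% worst-window identity, colinear truly-identical 200-nt
regions are still recovered at 100%). Segment calling uses full windows
only; a truncated tail window is reported in the track, flagged, but a
chance-qualifying 20-nt tail is not evidence of a "70% over 100 bp" signal.

## qPCR arithmetic

The quantification module implements the standard relative and absolute
qPCR calculations: replicate Cts are averaged (mean of Ct, per standard
practice with duplicate designs), `dCt = Ct_target - Ct_reference` per
sample, `ddCt = dCt_sample - dCt_calibrator`, relative expression
`2^-ddCt`; per-experiment max-normalization (values in (0, 1]) and
population-SD z-scores for combining runs; least-squares standard curves on
log10 dilution series with efficiency `10^(-1/slope) - 1` (slope -3.3219 =
perfect doubling); absolute copies `reference_copies *
10^((Ct - intercept)/slope)`; copies per cell and nuclear fraction as
guarded ratios. The cells-per-input conversion is an explicit argument
because it is assay-specific.

## Synthetic data: what it emulates, and what it does not

All tests run on generated data, so the generators define the study
conditions:

* `make_background(n, length_range = c(500, 4000), gc = 0.5)` emulates a
  species-wide lncRNA set used both as normalization background and target
  population. Defaults: 200 sequences for screens, lengths spanning
  realistic lncRNA transcripts.
* `make_convergent_pair()` plants a convergent pair: a 600-nt query and a
  6x longer partner assembled by sampling the query's 6-mers in permuted
  order (5% random noise 6-mers), with any residual shared exact run >= 20
  nt destroyed by local permutation. Composition transplanted, order not —
  the operational definition of "related motif content without linear
  similarity". The 6x ratio mirrors convergent pairs whose partners are
  severalfold longer. With `check = TRUE` the generator verifies its own
  guarantees through independent pipeline calls (99th-percentile all-k
  gate; zero conserved segments), and the test suite re-checks both rather
  than trusting the generator.
* `make_structure_pair()` embeds an identical 150-nt segment at a recorded
  position inside a 6x longer random context; under any deterministic
  backend the embedded region's profile locally matches the standalone
  segment's, so the true interval scores OBE recovery.
* `make_coding_pair()` builds a transcript with a complete 600-nt
  codon-biased ORF and pairs it with its own dinucleotide shuffle,
  regenerated until no >= 300-nt ORF survives — identical composition,
  opposite labels.
* `make_ct_fixture()` inverts the ddCt formula with duplicate measurements
  and optional Gaussian Ct noise.

These generators produce i.i.d. composition-homogeneous sequences. Real
lncRNA populations have repeat content, GC heterogeneity, shared
transposon-derived fragments, and phylogenetic correlation structure, none
of which is simulated. Passing the recovery tests therefore shows that the
algorithms do what they claim on data satisfying their own assumptions —
it does not show that the thresholds (99th/96th percentile, 0.095, 70%)
have the same operating characteristics on real transcriptomes.

## Numerical and design choices

* Intervals are 0-based half-open everywhere (match intervals, ORFs, BED
  output), matching BED conventions.
* Dinkelbach convergence tolerance 1e-12 on the ratio; DP tie-breaks as
  above; p-value floor `1/(n_shuffles + 1)` by construction.
* Randomness flows through explicit integer `seed` arguments (`set.seed`
  at generator entry), the R idiom for reproducible simulation; every
  generator is byte-identical across runs for a fixed seed.
* The funnel evaluates structure and linear stages only for candidates
  surviving the k-mer, coding, and reciprocal gates (`run_all_stages`
  overrides).
* The coding filter is applied to every surviving candidate, not only to
  selected ones.
* Problem sizes in the test and acceptance runs are scaled to desk scale
  as the package's own choice of study condition: 200-sequence
  backgrounds, 10 screen seeds, 99 shuffles for embedded-pair nulls, 19
  shuffles and 100/400-nt geometry for the 50-run null-uniformity
  experiment, 5 structural seeds in the acceptance script.

## Known limitations

* The default structure backend is an equilibrium pairing-propensity
  model; distances printed by trained structure predictors are not
  bit-reproducible here, and published headline distances (e.g. 0.087 with
  p = 0.001) should be reproduced with the original predictor's profiles
  supplied via TSV.
* The coding filter is a stand-in, calibrated for gating, not for
  benchmarking against SVM-based classifiers.
* The linear-homology stage substitutes a stiff-gap global aligner for
  anchor-based genomic alignment; it is a negative control, not a synteny
  tool.
* Screens are O(n_targets x 4^k) in memory at k = 6 per background fit;
  genome-scale target sets should be chunked.
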