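---
title: "Common orthologous regions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common orthologous regions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corexpr)
```

## The problem and the model

Comparing wound-healing (or any) time courses between a de novo assembled
transcriptome and a reference transcriptome faces two confounders: the two
species' genes are represented by different sequence universes (fragmented
isoforms vs curated transcripts), and basal expression levels differ between
species, so comparing per-species fold changes can mislead. The CORE
approach addresses both by restricting counting to *common orthologous
regions*: the sequence that BLAST can align between reciprocal best-hit
orthologs. Reads from both species are counted over homologous sequence
only, making the resulting gene-level counts directly comparable in one
model.

The combined design is a cell-means (group-means) linear model on log-CPM
with one coefficient per species-by-day cell. Comparisons are explicit
contrast vectors; the headline contrast is the species-by-time interaction

\[ (A_{d} - A_{0}) - (B_{d} - B_{0}), \]

the difference between the two species' time responses, which is immune to
species-level baseline offsets. Cell-means coding was chosen over
intercept/effects coding because it makes this difference-of-differences a
literal vector over named columns and leaves no intercept ambiguity.

### Orthology

A pair (geneA, geneB) is accepted iff (i) some isoform of the Trinity gene
geneA has its best forward hit on a transcript of geneB and (ii) that
transcript's best reverse hit lands on *any* isoform of the same geneA.
Reciprocity is enforced at the gene level on the de novo side: a de novo
assembler splits one gene into several isoforms, and demanding that the
reverse hit return to the *same* isoform would reject genuine orthologs on
an assembly artifact. The best hit is ranked by summed bitscore over all
HSPs to a subject (a single HSP understates split alignments), then minimum
E-value, then total aligned length, then subject id — a fixed chain so the
result is deterministic and invariant to input row order. A reference gene
claimed by several Trinity genes is kept and flagged (`shared_reference`):
de novo assemblies contain far more contigs than the reference has genes,
and downstream counting is keyed by the gene–transcript map anyway. When
one Trinity gene reciprocates with two reference transcripts, the pair with
the larger summed supporting bitscore is kept so each geneA appears once.

### CORE intervals

BLAST reports 1-based inclusive coordinates; BED is 0-based half-open, so a
query HSP `qstart..qend` becomes `(qstart-1, qend)` and the subject interval
is orientation-normalized with strand `-` when `sstart > send`. Intervals
are merged per (transcript, pair) independently on each side — there is no
base-level pairing requirement between the two species' intervals because
filtering is per species anyway — and subject-side intervals from different
isoforms of one pair are merged together, since counting is gene-level.
Book-ended intervals coalesce.

### Filtering and counting

A record passes when it is primary, mapped, non-supplementary, and its
reference span (CIGAR operations M/D/N/=/X) overlaps the union of its
transcript's CORE intervals by at least `min_overlap` bases (default 1) and
at least `min_overlap_frac` of its aligned length (default 0). Both knobs
are exposed because the choice materially changes counts near interval
edges. Counting is direct: one count per retained primary record, collapsed
to the gene label through the map; reads multi-mapping across isoforms of
one gene are harmless after the collapse, and cross-gene multi-mapping
resolution (an EM quantifier's job) is deliberately out of scope.

### The expression engine

* **Filter**: genes need `min_cpm` (default 10) CPM — converted to a count
  cutoff against the *average* library size — in at least `min_samples`
  (default 3) samples.
* **TMM**: reference sample = the one whose upper-quartile count fraction is
  closest to the mean; M and A values doubly trimmed (30% / 5%);
  precision-weighted mean of the retained M values; factors rescaled to
  geometric mean 1.
* **Precision weights**: logCPM = `log2((count + 0.5) / (lib*factor + 1) *
  1e6)` (the standard offset convention); sqrt residual SD is smoothed
  against mean log2 count by lowess (span 0.5) and inverted to
  observation weights `trend^-4`, clipped at 1e-6.
* **Moderation**: the scaled inverse-chi-square prior on residual variances
  is fitted by matching moments of `log s^2` (digamma/trigamma inversion,
  Newton solve); the posterior variance is `(d0 s0^2 + dg sg^2)/(d0 + dg)`.
  If all variances are equal the prior is degenerate (`d0 = Inf`) and every
  gene uses `s0^2`; `prior_df = 0` recovers the ordinary t exactly, which
  the tests exercise as a limit check.

Two numerical caveats worth knowing. First, the offset constants make the
transform only asymptotically depth-equivariant: doubling every library
changes each logCPM by `O(1/count)`, so the exact-invariance tests run at
deep coverage where that perturbation is below 1e-8. Second, sample-level
quality weights are not implemented; the per-observation weights come from
the mean–variance trend only.

### Threshold selection

Candidate thresholds (default grid 0.99 down to 0.70 in steps of 0.002,
which includes 0.914) are evaluated on the |Spearman| graph. A candidate
passes when the log-log degree regression has exponent in (1, 3) with R² at
least 0.8, the mean clustering coefficient is at least twice the
Erdős–Rényi baseline `k̄/n`, and the mean path length (largest component)
is at most the baseline `ln(n)/ln(k̄)`. Among passing candidates the
*lowest* is selected: it maximizes the fraction of genes retained in the
network while still satisfying the topology, and the rule is configurable
to `highest` for a more conservative graph. Edges use |rho| by default
(sign-agnostic co-expression; a signed variant is a toggle). The full
per-threshold report (threshold, R², slope, MeanCC, MeanPath, baselines,
%Used, %BigComp, pass) is always returned, and a matrix where nothing
passes yields an explicit `no_passing_threshold` status rather than a
guess.

The least-squares degree fit is kept deliberately faithful to the simple
log-log regression convention — including its known statistical weaknesses
(heteroscedastic log-counts, unweighted singleton tail points) — because
its role is threshold *selection*; the inferential claim about the degree
distribution is delegated to the likelihood machinery below.

### Power-law inference

The discrete power law `p_k = k^-alpha / zeta(alpha, xmin)` is normalized
with the Hurwitz zeta function, computed by a 20-term partial sum plus
Euler–Maclaurin tail correction (absolute error far below the optimizer's
1e-5 tolerance). `alpha` is estimated by numerical likelihood maximization
on (1, 8]; free `xmin` is chosen to minimize the KS distance between the
tail empirical CDF and the fitted law, scanning the observed unique values
(thinned to at most 75 candidates for speed). Goodness of fit is a
semi-parametric bootstrap: each replicate resamples the body empirically
and the tail from the fitted law, refits both parameters from scratch, and
the p-value is the fraction of replicate KS distances at least as large as
the observed one. The estimator's recovery and the test's calibration and
power are exercised in the acceptance tests at the sizes stated there
(alpha recovery at n = 1e5; calibration over 20 runs of n = 1000 with 200
bootstrap replicates; power against a geometric tail at n = 1e4).

One practical point: with a free `xmin` and no tail-size floor, the search
can discard essentially all of a non-power-law sample and fit the last few
dozen points, where almost anything looks like a power law — the GOF test
then has no power. The `min_tail` parameter (default 10, the bare minimum
for estimation) should be raised to a few percent of the sample when the
test is used for model *rejection*; the power checks use 5%.

### Subnetworks and factor plots

A subnetwork is the center gene plus its direct network neighbors that
appear in the regulator/target list (case-insensitive symbol match, since
mouse-style `Dmd` and human-style `DMD` conventions differ across sources),
with the induced edges; only direct neighbors are admitted. Subnetworks
with at least 10 members are flagged as of particular interest. Factor
plots summarize `log2(x + 1)` — the +1 offset keeps zero expression at
zero — with t-based 95% intervals, because group sizes in this kind of
design are small (3–4 replicates) and normal intervals would undercover.

## What the generators emulate — and what they do not

Every pipeline input has a deterministic simulator with known ground truth
(`simulate_ortholog_transcriptomes`, `simulate_blast_tables`,
`simulate_alignments`, `simulate_counts`, `simulate_coexpression`,
`simulate_powerlaw_degrees`); identical seeds give identical bytes, and
generated coordinates always respect generated sequence lengths.

* Transcriptomes: substitutions are uniform over the four bases
  (Jukes–Cantor-style, so the expected observed mismatch rate is
  `0.75 * divergence`); indels are single-base. Real divergence is neither
  uniform along the sequence nor free of large indels and paralogy.
* Hit tables: true alignments may split into 2–3 HSPs; decoys carry summed
  bitscores strictly below 0.8x the true pair's, so RBH ground truth is
  well-defined at generation time. Harder regimes come from raising
  `decoy_rate` and `divergence`, not from overlapping score ranges — the
  simulators never make the truth ambiguous, which real paralog-rich data
  can.
* Alignments: in-CORE reads are placed wholly inside intervals and
  off-target reads on reference sequences absent from the BED, so the
  planted retention fraction is exact. Real filtering also faces reads
  partially overlapping interval edges; the overlap knobs exist for that,
  but the generators do not produce such reads.
* Counts: NB with `var = mu + phi mu^2`, per-sample scale factors within
  2-fold, and the planted effect purely on the species-by-time interaction.
  No batch structure, no outlier samples, no length bias.
* Co-expression: module genes load on a latent factor with the loading
  chosen through the Gaussian rank-correlation relation
  `rho_S = (6/pi) asin(rho_P / 2)` so the *Spearman* correlation hits
  `within_r`; per-block noise is QR-orthonormalized in sample space so the
  within-block Pearson correlation is exact and only the rank-conversion
  wobble (~1/sqrt(n_samples)) remains. Hub-and-spoke "star" groups supply
  the degree-1 mass (leaves) and the heavy upper tail (hubs) — hub–leaf
  correlation just above `within_r`, leaf–leaf well below — and module
  sizes 3–7 continue the `k^-2` count line, so the thresholded degree
  distribution decays smoothly, as real co-expression networks do. Bridge
  hubs connect larger module pairs through correlated factors. The default
  `n_samples = 500` keeps the rank wobble (~0.005) small relative to the
  separation between the planted correlation levels; with far fewer
  samples the module boundary smears and no sharp threshold can recover
  the planted cliques — a real limitation of threshold selection on small
  designs, not just of the fixture. What passing tests on this fixture do
  *not* show: behavior under correlated noise across modules,
  non-Gaussian marginals, or the weak, dense correlation structure of real
  expression data.

## Problem sizes used in the tests

The test-suite fixtures are sized for completeness of coverage, not
realism of scale: 50 ortholog pairs (5 seeds) for RBH/CORE oracles, 1e4
alignment records for the filter oracle, 2000 genes x 6 groups x 4
replicates for DE calibration, ~560 genes x 500 samples for threshold
selection, n = 1e5 for exponent recovery, and 20 x 200 bootstrap
replicates for GOF calibration. `scripts/acceptance.R` re-runs the same
computations from a single command-line seed.

## Known limitations

* Counting is direct (primary records in intervals); no EM-based isoform
  quantification, so per se abundance estimation should use a dedicated
  quantifier.
* Single-end records only; paired input is accepted with a warning and
  mates are treated independently.
* The combined model shares one mean–variance trend across species; if the
  two species' libraries have very different technical quality this is a
  simplification.
* Threshold selection evaluates a finite grid; the report always shows the
  full grid so a user can see how sharp the pass region is.
* The subnetwork stage consumes regulator/target lists produced elsewhere;
  no enrichment statistics are computed here.
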