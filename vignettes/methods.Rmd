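---
title: "Detecting phased nucleosome arrays and ranking candidate repressors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phased nucleosome arrays and ranking candidate repressors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nurepress)
library(dplyr)
```

## The problem

Most regulatory-inference frameworks are built around open chromatin and
are therefore good at finding activators and poor at finding repressors.
Inside repressive chromatin domains (H3K27me3-marked Polycomb domains
being the motivating case), regulatory information is carried not by
accessibility peaks but by the *organization* of nucleosomes: runs of
regularly spaced, well-positioned, strongly occupied nucleosomes —
well-phased arrays. `nurepress` treats these arrays as discrete
structural units and asks, for each accessibility-defined subtype of
array, (i) how strongly the subtype is associated with transcriptional
downregulation and (ii) which transcription-factor motifs are enriched
at characteristic distances from the array, combining the two into a
ranked list of candidate repressors.

The intended user has, per sample: a DANPOS-compatible nucleosome call
table derived from repressive-mark ChIP-seq, repressive-domain peak
intervals, ATAC-seq fragments, gene models, an expression table, a PWM
library and the genome sequence. Everything in the package operates on
tibbles so stages compose with ordinary dplyr pipelines.

## Stage 1 — well-phased array detection

Each candidate run of nucleosomes is scored against five criteria:

* every summit-to-summit spacing within 160–220 bp (the canonical
  nucleosome repeat length range; `--spacing-on-mean` relaxes this to
  the mean spacing),
* coefficient of variation of spacings below 0.15,
* mean and minimum occupancy signal above the genome-wide 30th and 20th
  percentiles,
* maximum positional fuzziness below the genome-wide 20th percentile.

Two algorithms produce candidate arrays. The *sliding-window* algorithm
evaluates every window of `window_k = 3` consecutive nucleosomes, merges
passing windows whose genomic spans overlap or sit within 200 bp, and
re-applies all criteria to the merged run (merged candidates include
every bridged nucleosome, so a locally compliant pair of windows whose
union has irregular internal spacing is rejected in the second round).
The *seed-and-extend* algorithm (the default) takes greedy left-to-right
non-overlapping passing windows as seeds and grows each one nucleosome
at a time, always on the side with the greater improvement in array
quality, under criteria loosened by a factor of 1.2; a rejected
candidate nucleosome is consumed and a side closes after two consecutive
rejections.

Numerical choices worth knowing:

* **CV** uses the population standard deviation; the CV of a single
  spacing is 0. This keeps the default 3-nucleosome window (2 spacings)
  well defined and stable.
* **Percentiles** are linear-interpolation (type 7) percentiles, always
  computed on the full input table, never on a subset.
* **Relaxation direction.** "1.2× relaxed" is applied per criterion in
  whichever direction loosens it: the spacing window is widened
  symmetrically by 1.2× its half-width, `cv_max` and the fuzziness
  ceiling are multiplied by 1.2, the signal floors divided by 1.2. Any
  other reading would make extension stricter than seeding.
* **Array quality** for choosing the extension side is the negated
  spacing CV, with ties broken by higher mean signal and then the left
  side. Quality is deliberately simple and documented rather than
  clever.
* **Final re-check.** An extended array is re-tested against the
  *unrelaxed* criteria; failing extensions are reverted most-recent
  first until the array passes (the seed itself always passes). This
  guarantees the package-wide invariant that every returned array
  passes the full criteria, without discarding valid seeds.
* Arrays must overlap repressive-domain peaks by ≥ 30% of their length;
  surviving arrays are deduplicated and overlapping ones merged with
  statistics recomputed.

## Stage 2 — accessibility features and subtyping

Tn5 insertion events are extracted from ATAC fragments (+4/−5 end
shifts, the community convention; the shift is configurable because the
choice is not canonical), CPM-normalized, and summarized per array: the
body is cut into 100 near-equal bins (remainder spread over leading
bins) and each flank extends 1000 bp, clipped at chromosome bounds with
the clipped width as denominator.

Two features place each array in a plane:

* **IAE** (internal accessibility enrichment)
  `log2((inside + ε) / ((left + right)/2 + ε))` — negative means a
  closed interior;
* **BPS** (boundary polarity strength) `log2((right + ε)/(left + ε))` —
  magnitude measures flank asymmetry.

with `ε = 1e-9` guarding zeros. Both are z-scored within sample
(population SD) before clustering.

Subtypes come from a Gaussian mixture fitted by EM in the standardized
IAE–BPS plane. The EM is implemented in the package because the
subtyping contract requires seeded multi-start initialization (10
restarts, best final log-likelihood), a per-iteration log-likelihood
trace (asserted monotone in the tests), a 1e-6 convergence tolerance
with a 500-iteration cap, and ridge regularization (1e-6) of degenerate
components; `mclust`, which would otherwise be the natural backend,
serves instead as an independent cross-check in the test suite. For each
candidate k, full- and diagonal-covariance fits compete by BIC; across
k = 2..6 the winner is the k maximizing the mean silhouette coefficient
of the hard assignments (ties to the smaller k). Splitting the model
selection this way — BIC for covariance structure within k, silhouette
for k — honors both selection principles that reasonably apply here;
it is a design choice, flagged as such.

Cluster names are anchored to the two phenotypes and therefore stable
across seeds: `C1` is the component with the lowest mean standardized
IAE — the *boundary-transition* archetype (closed interior, accessible
flanks, IAE ≪ 0) — and `C2` the component with the highest — the
*accessibility-uniform* archetype (IAE ≈ 0). When more than two
components are selected, intermediates are named `C3..Ck` in ascending
IAE order, so the two named phenotypes keep their meaning whatever k
is. Raw mixture indices never appear in outputs.

## Stage 3 — union regions and state transitions

To compare samples, arrays from all samples overlapping by at least 50%
of the shorter array are chained into connected components; each
component becomes a union region spanning the coordinate union. The
overlap denominator (shorter array) is a documented choice —
`min_overlap` and the construction are symmetric in sample order. One
member per sample per region is enforced (greatest overlap with the
union wins, ties to the longer array; losers become their own regions)
so the per-sample state — `None` or the member's subtype — is
single-valued. A `(k+1) × (k+1)` transition matrix counts regions by
(state in A, state in B); row and column sums reproduce the per-sample
state counts by construction.

A binary promoter matrix `Q` marks ≥ 1 bp overlap between an item
(array or region) and a gene promoter. Promoters default to TSS ± 1000
bp (configurable, recorded in run metadata since every downstream
quantity depends on it), one promoter per gene id (first TSS in file
order).

## Stage 4 — repressive efficacy, motif enrichment, ranking

**Repressive efficacy (RE).** Within a sample, genes split into those
whose promoters contain *only* subtype-c arrays and those whose
promoters contain no arrays at all. With `Δ` the difference of median
expression (exclusive − absent) and `p` the one-sided Wilcoxon rank-sum
p-value (exclusive lower), `RE = |Δ| · (−log10 p)` when `Δ < 0`, else 0;
RE is *absent*, not zero, when either group is empty. Expression enters
as caller-provided linear-scale values (TPM-like); the package does not
impose units. The rank-sum test is exact by enumeration whenever
`choose(m+n, min(m,n)) ≤ 2e5` (ties handled via midranks), exact via the
null Mann–Whitney distribution when tie-free, and a tie- and
continuity-corrected normal approximation otherwise. The downregulation
indicator for the A→B contrast uses `log2((E_B + 1)/(E_A + 1)) ≤ −1`;
both the pseudocount and the cutoff are configuration.

**Motif analysis.** The phasing boundary of an array is the edge with
the steeper occupancy decline (outermost 200 bp inside minus adjacent
200 bp outside; ties to the left). Scan regions are the internal linkers
plus five contiguous 200-bp windows stepping outward from the boundary
(offsets 0–1000 bp). The foreground for subtype c follows the
promoter-fraction rule: when more than 20% of the subtype's arrays
overlap promoters, only transitioning arrays whose promoter genes are
downregulated are scanned (this can legitimately be empty, with a
warning); otherwise all subtype-c arrays are used to preserve power.

The scanning engine is internal: log-odds PWM scores on both strands,
with a per-TF threshold computed by exact dynamic programming over the
discretized score distribution under the background model (0.01-bit
bins, target p ≤ 1e-4 per position). Backgrounds are sampled 10:1,
length-matched and GC-matched in 5% bins, excluding the foreground ± 1
kb, with a fixed recorded seed; draws that cannot be GC-matched within
50 attempts are accepted and counted. Enrichment per TF per window
label is a one-sided hypergeometric test over the pooled
foreground + background universe, BH-adjusted across TFs within each
label. A parser for HOMER `knownResults.txt` is provided for users who
prefer that backend's precomputed output.

**Scores.** `MP` is the maximum `−log10(adjusted p)` across window
labels — by default including the linker label pooled with the boundary
windows (a flag restricts to boundary windows only, since the two
readings are both defensible). `RPS = RE × MP` ranks TFs within a
subtype; a TF is a candidate when `RE > 0` and `MP > −log10(0.05)`. The
specificity score `S = MP_c − max_{c' ≠ c} MP_{c'}` (missing MPs count
as 0) separates subtype-specific candidates from subtype-shared ones
and is reported descriptively, never used as a filter.

On the full pancreatic-progression datasets this workflow reports RE
values per subtype per cell line (boundary-transition arrays low, ~4–6;
accessibility-uniform arrays high, ~46–62) and k = 2 in every sample;
reproducing those numbers requires downloading the public ChIP/ATAC/RNA
data and running nucleosome calling, which is outside this package's
offline scope. All offline quantities in this vignette and the README
are computed by the test suite or `scripts/acceptance.R`.

## The synthetic landscape generator

`simulate_landscape()` builds, deterministically per seed, the complete
input set at toy scale: one 2 Mb chromosome, 20 repressive domains of 8
kb, 40 planted arrays (5–10 nucleosomes, spacing N(185, 4) truncated,
signal 3× the decoy level, fuzziness constructed to sit below the
global 20th percentile), 1500 decoy nucleosomes that each violate at
least one criterion, an ATAC fragment library whose insertion rates
encode the two archetypes (C1: flanks boosted 6×, interior background,
with a mild lognormal left/right asymmetry of sd 0.15; C2: uniform 3×
boost over body and flanks), 200 genes (40% of arrays host a promoter
gene; the rest sit between domains), two expression samples in which
C2-hosted genes are reduced 8-fold in sample B, and a PWM library whose
first motif is planted at 120/320/520 bp beyond both edges of every
repressed-gene C2 array. One RNG stream per component derives from the
master seed, so changing one component's parameters leaves the others'
draws unchanged.

Two generator parameters deserve an explicit rationale. The C1 flank
asymmetry is kept small (lognormal sd 0.15, giving a BPS spread about
twice the counting noise of C2) because the generator's contract is a
*two*-archetype structure: a larger asymmetry turns BPS into a second
clustering axis, and silhouette — correctly — prefers to split the
elongated C1 cloud, which is a property of the data, not of the
selector. Second, the feature-level subtype-recovery tests use 100
synthetic arrays per archetype with per-cluster noise matched to what
the insertion model produces at the default depth (IAE/BPS SDs
0.3–0.5); at materially smaller cohorts the k = 2 versus k = 3
silhouettes differ by less than 0.01 and the comparison measures
sampling noise rather than the selector.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: mappability and copy-number artifacts, Tn5
sequence bias (GC matching of backgrounds is exercised, but the
foreground signal itself is bias-free), fragment-length nucleosome
footprints, overlapping or alternative promoters, inter-chromosomal
structure, and replicate-level biological variability. Problem sizes
throughout (2 Mb, 40 arrays, 200 genes, 20 seeds) are the package's
simulation design for a full pipeline run in tens of seconds.

## Known limitations

* One sample per detection run; cross-condition nucleosome calls must
  be processed sample by sample before union-region construction.
* The transition matrix is descriptive; no test statistic is attached.
* The motif engine scans known PWMs only; de novo discovery is out of
  scope, as are BAM-level operations and visualization beyond the
  provided ggplot helpers.
* Defaults were established in an H3K27me3 context; other repressive
  marks will likely need different spacing/percentile settings.
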