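---
title: "Detecting misassemblies from mate-pair insert sizes"
author: "mpRepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting misassemblies from mate-pair insert sizes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpRepair)
```

## The model

A long-insert mate-pair library carries linkage information over several
kilobases. When those pairs are aligned back to the draft assembly they
came from, a correctly assembled region shows pairs at the expected
insert size and orientation; a large misassembly — a junction joining
unrelated loci, or a large indel — shows pairs with anomalous inserts,
wrong orientations, or mates lost to other contigs.

mpRepair models an observed insert size $Y$ as a two-component mixture.
The null component is normal, $Y \sim N(\hat\mu, \hat\sigma^2)$. The
anomaly component is uniform over the contig, $U(0, L)$: it assumes
nothing about what caused the anomaly, and it is bounded by the contig
because only pairs with both mates on the contig are scored. For a pair
$l$ with insert $Y_l$, the posterior probability of the null class is

$$P(X_l = 1 \mid Y_l) =
  \frac{\pi_1 f_N(Y_l;\hat\mu,\hat\sigma^2)}
       {\pi_1 f_N(Y_l;\hat\mu,\hat\sigma^2) + \pi_0 / L},$$

with $\pi_0$ the prior probability of an anomalous insert (default
0.01, i.e. 99% of pairs are expected to be null) and
$\pi_1 = 1 - \pi_0$.

At each evaluated position $i$ the *spanning* pairs are retrieved: one
read must end entirely before $i - W$ and the other begin entirely after
$i + W$ (strict inequalities against the closed window, default
$W = 200$). Their support is summed,

$$D_i = \sum_l P(X_l = 1 \mid Y_l)\, C_l,$$

where $C_l$ indicates correct pairing orientation; a wrongly oriented
pair contributes exactly zero. Within each contig the support values are
standardised,

$$z_i = \frac{D_i - \mu_D}{s_D}, \qquad
  \mu_D = \frac{1}{N}\sum_i D_i, \qquad
  s_D = \frac{1}{N}\sum_i \lvert D_i - \mu_D \rvert,$$

and positions with $z_i < T$ (default $T = -4$) are flagged. $s_D$ is a
mean absolute deviation, not a variance: we treat it as a scale
parameter, and the threshold is therefore expressed in units of mean
absolute deviation from the contig mean (for Gaussian noise,
$s_D \approx 0.8\,\mathrm{sd}$, so $T = -4$ corresponds to roughly
$-3.2$ standard deviations). Per-contig standardisation prevents
coverage differences between contigs from masking real anomalies or
manufacturing false ones; the price is reduced sensitivity on very
small contigs, which is why contigs below `minsize` are not scanned at
all.

## Global parameter estimation

$\hat\mu$ and $\hat\sigma$ are estimated once, across all contigs, from
pairs that pass the population filters: both mates on the same contig,
correct orientation for the configured library layout, insert at most
`maxinsert` (default 30 kb, roughly ten times a typical mate-pair
insert), and both mates with mapping quality at least `minmapq`
(default 40, excluding non-unique placements). $\hat\mu$ is the plain
arithmetic mean of the surviving inserts. The scale is robust:
$\hat\sigma = 1.4826 \times \mathrm{MAD}$, the median absolute deviation
scaled to be consistent with the standard deviation under normality.
Real mate-pair insert distributions have a long right tail; the MAD
ignores it where a naive standard deviation would inflate several-fold
and mask anomalies (the package's acceptance script demonstrates this on
a 1%-contaminated sample). Each pair contributes one insert value.
Medians of even-length samples are the mean of the two central order
statistics.

The insert size is the *outer* distance — leftmost aligned base of the
leftmost read to rightmost aligned base of the rightmost read — computed
from the alignment coordinates (CIGAR-aware reference extents) rather
than trusted from the template-length field. "Correct orientation" is a
library-layout setting (`fr` by default, `rf` available), because
mate-pair protocols differ in whether reads were flipped during
processing.

## The per-contig index

Each contig's pairs are read from the BAM exactly once and stored with
their spans, per-read extents and orientation flags; spanning queries
are served by an interval overlap lookup (IRanges' nested containment
list) followed by the strict per-read containment check. Mapping quality
is deliberately *not* filtered at this stage: a region where uniquely
mapping pairs vanish should register as lost support, not be hidden by
the filter. Per-read extents must be stored because the pair's outer
span alone cannot express "read ends entirely before the window".
Duplicate pairs at identical coordinates are retained.

## Calling, end exclusion and breaking

Flagged positions within the trimming distance (default `trim` = 4000
bases) of either contig end are discarded before merging. Contig ends
genuinely lose spanning support — near an end there is simply no room
for a full insert, and in real data mates fall on other contigs — so
end dips are expected under correct assembly; a circular molecule
assembled as a single contig would otherwise always be truncated.
Excluding ends *before* merging prevents an edge artefact from dragging
an interior call outward. Surviving positions closer than `trim` are
merged by single linkage into one call, to prevent excessive clipping
of adjacent detections.

Each call region, padded by `trim` on both sides and clamped to the
contig, is excised; if padded excision intervals overlap they are united
first, so total output length always equals input length minus the
excised total. Fragments are named `<contig>_0`, `<contig>_1`, … left to
right, and zero-length fragments are dropped. With `trim = 0` the contig
is still broken at the call boundaries, with merging and end exclusion
falling back to one `stepsize`, so breaking without sequence removal
remains possible.

## The simulator

`simulateDataset()` generates the conditions the detector assumes:
contigs of tens of kilobases to a megabase of i.i.d. uniform ACGT
sequence; mate pairs with normal inserts (defaults 3000 ± 300 bases,
reads of 150 bases) plus a small anomalous fraction (1% uniform inserts,
1% flipped strands); and, optionally, an engineered junction joining two
unrelated source sequences, with the truth coordinate recorded. Pairs
are placed on the *true* source coordinates: a pair whose fragment
straddles a junction keeps its left read while its right mate — whose
true locus does not exist on the contig — is re-mapped to a uniform
random position with random strand, reproducing the mixture of anomalous
inserts and wrong orientations a real aligner produces at a junction.
`spanningCoverage` (default 30) is the expected number of pairs whose
inter-read gap covers a position, so the support track averages slightly
below it once the detector's window is subtracted.

The simulator writes coordinate-sorted SAM text (mapq 60, full-length
match CIGARs, reciprocal mate fields); conversion to an indexed BAM is
left to `Rsamtools::asBam` or `samtools`. It does not emulate sequencing
errors or base qualities (the detector only reads coordinates, flags and
mapq), chimeric junction-adapter reads, GC-dependent coverage waves, or
repeat-induced mis-mapping. Passing tests on simulated data therefore
demonstrate the statistical machinery — robust estimation, spanning
retrieval, scoring, breaking — under the model's own assumptions, not
robustness to every artefact of a real library.

## Numerical and design choices

- The posterior is computed in log space
  (`plogis(log f_N + log π_1 − log(π_0/L))`), so an insert 20 standard
  deviations out underflows to posterior 0, never NaN.
- The evaluation grid starts at `stepsize` and skips positions within
  `window` of either contig end, so every query window fits inside the
  contig.
- If every position on a contig has identical support ($s_D = 0$) the
  Z-scores are defined as 0 and a degenerate-scale warning is recorded;
  a model with $\hat\sigma = 0$ (constant inserts) aborts the scan with
  a diagnostic instead of dividing by zero.
- $s_D$ uses divisor $N$, and $\mu_D$, $s_D$ range over the evaluated
  positions of the contig.
- A flagged position exactly at the trim distance from an end is treated
  as within the exclusion zone; this matters because a junction within
  an insert length of an end casts its support shadow up to roughly that
  boundary.
- Coordinates are 0-based half-open internally and in the scores CSV;
  FASTA output is wrapped at 80 columns.

## Problem sizes and expectations

The test suite and acceptance script run on 200 kb contigs at 30×
spanning coverage (about 2,200 pairs per contig, ~25 spanning pairs per
evaluated position), a scale at which a junction's support collapse is
unambiguous: the junction position scores $z \approx -5$ to $-6$ against
interior null fluctuations of $z > -4$. At the default threshold a clean
contig of this size still has on the order of a 10% chance of one false
flagged position; the default $T = -4$ trades a small false-positive
rate for sensitivity, and users concerned about over-breaking should
lower $T$. Very short contigs (below `minsize`, default 10 kb) are never
scanned: with few evaluated positions, $\mu_D$ and $s_D$ are too noisy
to standardise against.

## Known limitations

- Sensitivity is limited within an insert length of contig ends (by end
  exclusion) and on contigs near `minsize`.
- The anomaly prior $\pi_0$ is fixed, not estimated from the data.
- Only same-contig pairs are scored; errors are visible through lost
  support when mates map elsewhere, but inter-contig linkage is not
  itself modelled.
- Calls at adjacent bins inflate the binned false-positive count in ROC
  evaluation when a call region extends one bin past a point truth, an
  artefact of 1 kb binning rather than of the detector.
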