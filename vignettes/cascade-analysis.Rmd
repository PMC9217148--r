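---
title: "Reconstructing and analysing microblog repost cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and analysing microblog repost cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repostcascade)
```

## The problem

On microblog platforms of the Weibo type, a repost carries the whole
history of its forwarding path inside its own text: each forwarder's
comment is prepended and the segments are separated by `//`, with an
`@handle:` mention naming the user whose repost was forwarded. A raw
repost table therefore contains enough information to reconstruct, for
every original post, the *dissemination tree* of who forwarded whom —
and from that tree, how far, how wide and how fast a claim travelled.
This package implements that reconstruction and the downstream analyses
for studying health-misinformation diffusion: cascade topology metrics,
a structural typology of cascades, authority-based segmentation of the
users who post misinformation, and rank correlations between a
creator's authority and the reach of their posts.

## From chain text to tree

`extract_level()` counts `//`-delimited segments: a direct repost of the
root carries one segment (its own comment, possibly empty), a repost of
a repost two, and so on, so level equals segment count with the root
post at level 0. Separator occurrences inside quoted text are not
special-cased; on this platform `//` is a reliable delimiter, and
treating it as such keeps the rule deterministic.

`resolve_parents()` attaches each level-k record (k > 1) to the
level-(k−1) record whose reposter matches the leading `@handle:`
mention of its second chain segment, with case-sensitive exact
matching. Two deliberate choices:

* **Ambiguity** (two candidate parents with the same handle and level)
  resolves to the nearest earlier timestamp, then the smallest repost
  id — fully deterministic.
* **Orphans** — records whose intermediate parent was deleted or
  blocked before capture — are dropped and counted, *not* re-attached
  to the root. Re-attachment would deflate depth and inflate
  first-level width, which would bias cascades toward the radiation
  class; dropping mirrors the exclusion of uncapturable posts from the
  original data collection. Children of orphans are orphaned too, so
  the resolved edge set is always a forest with consistent levels.

## Topology metrics

With $w_\ell$ nodes at forwarding level $\ell = 1,\dots,d$: scale
$= \sum w_\ell$ (reposts only — the nine-node worked example in
`toy_cascade()` has 9 nodes but scale 8, which fixes the convention),
depth $= d$, maximum width $= \max_\ell w_\ell$, and average width
$=$ scale$/d$, the mean over repost levels only; averaging over levels
$0..d$ would break the identity avg width × depth = scale and could
exceed the maximum width. These identities hold exactly and are tested
on every simulated cascade.

**Speed** has no canonical definition in this literature; here it is
reposts per hour over the cascade's lifetime (root timestamp to latest
repost), with elapsed time floored at one minute — the declared
timestamp resolution — to avoid division by zero when an entire cascade
falls within the root's minute. Undisseminated posts have missing
speed, not zero: zero would mean "spread infinitely slowly", which is a
different statement from "did not spread".

## Structural typology

A cascade is **radiation** when its first forwarding level is at least
as wide as every deeper level. The comparison is `>=`, not `>`: depth-1
cascades and width ties are radiation, since a tie means no deeper
level out-spread the direct audience. Otherwise secondary hubs carried
the spread, and the class depends on engagement: the printed rules name
"the node with the highest forwarding volume" and "the node with the
highest like volume", which can be different nodes with conflicting
verdicts. The implementation collapses both to a single *pivot* — the
repost node maximising the larger of its forwards and likes, ties
broken by larger forwards, then earlier timestamp, then id — and labels
the cascade **sector** when the pivot's forwards ≥ likes, **viral**
otherwise. Posts with no reposts are **undisseminated**, so the four
labels partition all cascades.

## User segmentation

The five authority features are user level (0–48), membership level
(0–7) and posts/followers/following counts. Follower counts are heavy
tailed (means in the tens of thousands are realistic), so the three
count features are `log1p`-transformed before z-scoring; without the
transform, follower count alone would dominate Euclidean distance.
Zero-variance features are dropped with a warning rather than silently
producing NaN scores.

Clustering is Lloyd k-means started from deterministic farthest-point
seeding (first centre drawn under the seed, each next centre the point
farthest from those chosen), so a fixed seed reproduces assignments
exactly; should a cluster empty, the run falls back to seeded random
restarts.

**Choosing k.** The elbow criterion is formalised as the k maximising
the second difference of the within-cluster sum of squares,
$W(k-1) - 2W(k) + W(k+1)$. Because that expression needs both
neighbours, the WCSS curve is extended one k beyond each end of the
candidate range — down to $k=1$, where $W$ is the total sum of squares
and needs no clustering, and up by one extra k-means fit — so every
candidate, including the smallest, is eligible. Mean silhouette width
is reported alongside as a diagnostic. One property of this (or any
curvature-based) criterion is worth knowing: it finds the *sharpest*
bend. If the population is hierarchically separated — one large group
far from all others, as with a dominant inactive mass — the sharpest
bend can legitimately sit at k=2 even when five planted subgroups
exist; with roughly equidistant, comparably sized groups the criterion
recovers the planted count. Fixing k explicitly (`k = 5`) is the right
call when the downstream archetype naming is wanted.

**Naming.** The five archetypes are assigned by ordered centroid
comparisons (on the original scale, counts compared on the log scale):
influential = largest posts + followers profile; mingler = of the rest,
many followers but few posts; inactive = lowest on everything;
remaining two split on membership level (platform higher, general
lower). These rules are reverse-engineered heuristics from verbal
cluster descriptions, not a fitted model; exact centroid ties leave the
naming unresolved with a warning rather than guessing.

## Association statistics

* **Spearman's rho** is the Pearson correlation of midranks, with a
  two-sided p from the t approximation — adequate at the corpus sizes
  this pipeline targets (hundreds to thousands of cascades) and
  well-defined under ties. The test suite checks equality with a
  brute-force midrank oracle to 1e−12 and that the null rejection rate
  at α = .05 stays within binomial bounds.
* The **correlation grid** crosses the five topology metrics with the
  five authority features, pairwise complete cases, at least 3 per
  cell; raw p-values are reported (as is conventional in this
  literature) with a Benjamini–Hochberg column alongside.
* **Per-topic summaries** use the standard t interval
  $\bar x \pm t_{0.975,\,n-1}\, s/\sqrt n$. The interval is exact under
  normality only; cascade scale is heavily skewed, so nominal 95%
  coverage is approached, not guaranteed, at small group sizes — the
  coverage test asserts a band, not the nominal value.
* **Time bins** are ISO weeks anchored on Mondays.
* **Krippendorff's alpha** (nominal) is computed from the coincidence
  matrix, with unpairable (single-coded) items dropped; perfect
  agreement yields exactly 1, and systematic disagreement goes
  negative. No installed package provides this statistic, so it is
  implemented here and tested against hand-built coincidence matrices.

## The synthetic corpus

`simulate_dataset()` exists so that the full pipeline — including the
fragile chain-text parsing — can be exercised end to end with known
ground truth. What it emulates, and the defaults:

* **Users**: five archetypes mixed in proportions 2342 / 2980 / 5652 /
  101 / 226 (general, platform, inactive, influential, mingler — the
  relative group sizes reported for this population), counts lognormal
  around archetype centroids, levels truncated Gaussian. Truth labels
  are returned beside, never inside, the dataset.
* **Topics** mixed at 8.92 / 5.58 / 46.80 / 36.09 / 2.61 per cent
  (government response, epidemic spread, medical, social/livelihood,
  international), with a mild archetype-dependent tilt so the
  archetype-by-topic crosstab has recoverable structure.
* **Cascades**: level-dependent Galton–Watson branching,
  Poisson($\lambda_k$) offspring per level-k node; regime mix
  97 / 1 / 2 per cent radiation / sector / viral. Radiation uses
  $\lambda = (8, 0.2, 0.1)$ — a wide first level, little beyond;
  sector/viral use $\lambda = (2, 0.8, 0.5, 0.3)$ plus one planted
  level-1 hub with mean 8 extra offspring, whose engagement favours
  forwards (sector) or likes (viral). The root author's follower count
  scales $\lambda_1$ by $\log(1+F)/\log(1+F_{\mathrm{ref}})$, planting
  the positive scale–followers rank correlation the correlation stage
  should detect.
* **Engagement**: negative binomial (size 0.4) with post-level means
  11 forwards / 13 comments / 189 likes — likes an order of magnitude
  above forwards, as observed on this platform. A post's recorded
  forwards count equals its generated cascade's scale.
* **Timing**: exponential inter-repost waits (mean 0.5 h), floored to
  the minute grid; root posts uniform over ten ISO weeks.
* Within one cascade, reposters are drawn **without replacement**, so
  every `@handle:` mention identifies a unique parent and the parser's
  reconstruction can be checked for exact equality against the true
  tree — which the acceptance suite does on a 1,000-cascade corpus.

What it does **not** emulate: real chain texts (comments are synthetic
tokens), users forwarding the same post twice, clock skew or missing
timestamps, deleted intermediate posts (orphan handling is tested with
explicitly truncated fixtures instead), and any fitting of the
generator to a real corpus. Passing tests therefore demonstrate the
pipeline's correctness on well-formed chains and its statistical
behaviour under the planted models — not robustness to every artefact
of a live crawl.

## Numerical and reporting conventions

Report percentages round half-up to two decimals (46.795 → "46.80"),
matching the convention of the descriptive tables this report format
follows; every printed percentage recomputes exactly from its printed
numerator and denominator. Timestamps are ISO-8601 at minute
resolution, UTC, and survive a write/read round trip byte-identically.
Rows violating type invariants are rejected with named reasons and
counted — accepted + rejected always equals input — rather than
silently dropped.

## Problem sizes

The test suite runs the generator at 400–4,000 users and 60–1,000
posts per case; the exact-equality generator↔parser comparison uses
1,000 cascades, typology recovery 500 radiation-regime cascades,
clustering recovery 2,500 users, and the null-calibration check 200
replicates at n = 100. These sizes give stable Monte-Carlo behaviour
for the planted effects while keeping a full run in the minutes range
on one core.

## Known limitations

* Handle matching assumes the `@handle:` mention equals the reposter
  id in the repost table; platforms where display names differ from
  ids need a handle column mapped in beforehand.
* The sector/viral pivot rule is one consistent reading of typology
  rules that are underspecified for conflicting argmax nodes.
* Speed's definition is package-chosen (see above); compare across
  datasets only with the same convention.
* Archetype naming is heuristic; with real data, inspect centroids
  before trusting labels.
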