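---
title: "Reconstructing the MetJ regulon: model, thresholds, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the MetJ regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metboxr)
```

## The problem

MetJ is the master repressor of methionine biosynthesis in the
gammaproteobacteria. One MetJ homodimer binds an 8-bp palindromic operator
box (a *metbox*); functional repression requires two or more dimers bound to
abutting boxes, so real operators are tandem arrays of boxes in the region
upstream of a regulated gene. Given genome sequences, gene annotations, and
a set of known or candidate boxes, `metboxr` reconstructs the regulon: which
gene families, in which species, carry a credible tandem metbox array in
their upstream DNA.

## The information weight matrix

The scoring model is a per-position log-frequency ("information weight")
matrix. For base $b$ at half-site position $l$,

$$R_{iw}(b, l) = \mu + \log_2 f(b, l), \qquad
  f(b, l) = \frac{n(b, l)}{N},$$

where $n(b, l)$ is the count of base $b$ at position $l$ over the $N$
half-sites used to build the matrix. With $\mu = 2 = \log_2 4$ bits — the
only value consistent with every cell of the bundled matrix, and the natural
choice for a 4-letter alphabet — a position with uniform composition scores
exactly 0 bits, enrichment above one quarter scores positive, depletion
negative.

Because the box is palindromic, the data are *symmetrized*: every 8-bp box
contributes its first four bases and the reverse complement of its last four
bases as two independent half-sites, and only the 4-position half matrix is
ever stored. The 8-column view used for scanning is derived on the fly
(position $p \in 5..8$ looks up the complemented base at position $9-p$), so
strand symmetry is structural: `score_window(m, w)` equals
`score_window(m, revcomp(w))` to the last bit of floating point, and the
scanner only needs one strand pass.

Numerical choices:

* **Pseudocount.** A zero count would give $-\infty$ bits; it is replaced by
  1 *while keeping the denominator at* $N$. With $N = 832$ this reproduces
  the printed $-7.70$ for the one zero cell; using $N + 1$ would too, at two
  decimals — the printed precision cannot distinguish them, and $N$ is
  simpler.
* **Ambiguity codes.** Anything outside A/C/G/T is read as `N`, and `N`
  scores the *worst* weight at its position — never a wildcard — so
  low-quality sequence cannot create hits.

```{r}
m <- metj_matrix()
m
```

## Thresholds and tandem-site calling

Both scan thresholds derive from one number, the consensus score $C$ (the
best possible window, equal to twice the sum of per-position maxima, and —
verified exhaustively over all $4^8$ windows in the test suite — the global
maximum of the window score):

* a single box is kept iff its score $\geq C/4$ (`tau_box`);
* a run of $\geq 2$ abutting boxes is a site iff its summed score
  $\geq C$ (`tau_site`).

"Abutting" means successive box starts differ by exactly 8 bp. The source
material does not pin the spacing down; tandem metbox arrays are
crystallographically 8-bp repeats, so exact-8 is the default and a
`spacing_tolerance` knob exists for exploration. Two further reading choices
are documented here because the text leaves them open: runs are *maximal*
(no sub-run rescue — any sub-run above `tau_site` implies the maximal run is
too, since all retained boxes score positive), and the site score sums the
*whole* run, not just its best two boxes. When two candidate runs overlap
out of phase, the higher-scoring run wins, ties going to the leftmost.

Upstream windows are 400 bp ending at the start codon, truncated (never
padded) at contig edges, and deliberately **not** clipped at neighboring
genes: automated annotation is unreliable, and a genuinely shared operator
between divergently transcribed genes must be visible from both — such sites
are reported once per gene with a `shared` flag.

## The two-stage bootstrap

The discovery pipeline (`discover()`) refines a small experimental seed into
a genome-wide matrix:

1. build the seed matrix from known boxes;
2. scan the upstream regions of known-regulon homologs in **one
   representative species per genus** (lexicographically first identifier;
   de-biasing against densely sequenced genera), with the seed matrix's own
   consensus-derived thresholds;
3. pool the two symmetrized half-sites of every box inside every passing
   site and build the final matrix from the pool;
4. rescan every gene of every species with the final matrix;
5. tally, per gene family and taxonomic order, how many species carry the
   gene and how many of those carry at least one called site.

Stage 2 keeps *all* boxes of passing sites (the "high-confidence" filter is
exactly the two-threshold rule; a stricter percentile filter is exposed as
configuration but off by default). The pipeline is deterministic given its
inputs, and runs exactly two stages — iterating further is out of scope by
design.

## Conservation tiers

For cross-species comparison, a called site is extended by 8 bp of flank on
each side (flanking DNA drifts faster, making the comparison conservative),
and percent identity against the reference species is computed **ungapped**:
column-wise when lengths match, otherwise the best sliding offset of the
shorter along the longer with the shorter length as denominator (so edge
truncation is not penalized). Gaps are biologically unexpected inside
fixed-period tandem arrays, and no gapped mode is provided. Tiers follow the
$\geq 70\%$ (strong) / $\geq 60\%$ (weak) / otherwise divergent rule, with
both boundaries inclusive.

## Reporter-assay utility

`miller_units()` implements the activity normalization exactly as printed,
`abs420 / (vol_ul * time_min * od600)` — note the absence of the classical
x1000 scaling, available via `classic = TRUE`. `repression_ratio()` is the
ratio of mean activities (repressor present / repressor deleted), with
standard deviation by first-order propagation
$\sigma \approx r\sqrt{(\sigma_r/\mu_r)^2 + (\sigma_d/\mu_d)^2}$; the source
phrase "shown with the standard deviation" is ambiguous, and propagation is
this package's documented choice.

## The synthetic world, and what a green test establishes

`generate_cohort()` builds what the pipeline consumes with a fully known
truth: single-contig species of i.i.d. background (GC fraction
configurable; there is no background model in the scoring, so an order-0
background is the matching null), genes tiled on alternating strands with
400-bp upstream windows, and a configurable fraction of genes (default 0.5)
receiving `k` abutting boxes (default 2) drawn from the planting matrix.

* **Fidelity.** Each planted base comes from the matrix's frequency model
  with probability `fidelity`, else uniform; each box's second half is the
  reverse complement of an independently drawn half, preserving the
  palindromic statistics. Fidelity 1.0 is the stated world for recovery
  benchmarks; the dose–response sweep drops it to 0.25.
* **Placement.** Distance from site end to start codon is
  $8 + \mathrm{Binomial}(134, 0.5)$ — bounded inside the window with mode
  ~75 bp, matching where real high-confidence sites concentrate; a uniform
  option exists.
* **Detectability.** A planting at fidelity 1.0 is a *draw* from the
  frequency model, not the consensus, and clears the two thresholds with
  probability only about 0.70 — a number you can get by exact enumeration
  of the 256 half-site scores, with no simulation:

```{r}
f <- iwm_frequencies(m); b <- m$bits
g <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
hs_score <- rowSums(matrix(b[cbind(as.vector(g), rep(1:4, each = nrow(g)))],
                           nrow(g)))
hs_prob <- apply(g, 1, function(i) prod(f[cbind(i, 1:4)]))
box_score <- as.vector(outer(hs_score, hs_score, "+"))
box_prob <- as.vector(outer(hs_prob, hs_prob))
thr <- scan_thresholds(m)
ok <- box_score >= thr$tau_box            # both boxes must pass tau_box
s <- box_score[ok][order(box_score[ok])]
p <- box_prob[ok][order(box_score[ok])]
tail_mass <- rev(cumsum(rev(p)))          # P(second box score >= s[i])
site_pass <- sum(p * tail_mass[pmax(1L, findInterval(
  thr$tau_site - s, s, left.open = TRUE) + 1L)])
site_pass
```

  No scanner can recover a sub-threshold planting, so
  `evaluate_recovery()` reports two numbers: `recall`, over *detectable*
  plantings (every box $\geq$ `tau_box`, total $\geq$ `tau_site` — the truth
  table stores the realized scores for exactly this purpose), which is the
  scanner-correctness figure the acceptance suite holds at $\geq 0.95$ with
  exact coordinates; and `recall_all`, over all plantings, which reflects
  the ~0.70 statistical power of the threshold rule at fidelity 1.0 and
  drives the fidelity dose–response check. The residual few percent lost
  from exact-coordinate recall comes from chance background windows landing
  in phase next to a planted pair: the maximal run then extends past the
  planted span — correct scanner behavior on an adversarial background, not
  a bug.

What the synthetic world does **not** emulate: real intergenic/coding
composition differences, phylogenetic correlation between species, operon
structure, indels, or annotation error. A green recovery test therefore
establishes the scanner and bootstrap machinery, not performance on real
genomes; the genome-scale counts printed for the original 206-species
analysis are deliberately out of reach at desk scale.

## Known limitations

* No statistical calibration of bit scores (no p-values, no background
  correction); thresholds are the consensus-derived rule only.
* Ortholog mapping is consumed as an input table; sequence-similarity
  searching is out of scope.
* Ungapped conservation only; divergent species beyond sliding-offset
  comparability come out as `divergent` rather than being aligned.
* The representative-per-genus policy is lexicographic for determinism, not
  phylogenetically informed.
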