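---
title: "Methods: chemical-cleavage nucleosome mapping, linker quantization, and the hard-rod positioning model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-cleavage nucleosome mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuclinker)
```

## The measurement this package models

An engineered cysteine on histone H3, coupled to phenanthroline-copper,
cleaves nucleosomal DNA at two fixed sites flanking the dyad. When both
sites of one nucleosome cut, a ~51-bp *intranucleosomal* fragment is
released whose midpoint is that single nucleosome's dyad — no averaging
over cells or Bayesian deconvolution is needed, which is what
distinguishes this chemistry from dyad-proximal cleavage mapping and from
MNase-seq. Fragments whose ends come from cuts in *neighbouring*
nucleosomes carry the dyad-to-dyad distance: cuts at the two
dyad-proximal sites give a "medium" fragment (repeat length minus 59 bp),
and cuts at alternate sites give a "long" fragment (repeat length minus
the few bp lost at one cleavage site). Because each cut destroys a fixed
number of base pairs (the *gap*), the nucleosome repeat length (NRL) is
the long-fragment length plus the gap.

The package implements the full downstream analysis of such an
experiment, plus a generative model of the chemistry so that every stage
can be exercised and validated without sequencing data.

## Coordinate and container conventions

All internal coordinates are 1-based and inclusive; BED input/output
(0-based, half-open) is converted only at the I/O boundary. Per-bp
signals (dyad counts, occupancy, model probabilities) live in a
`bp_profile`: a named list of numeric vectors, one per chromosome, with a
`normalized` flag. Dyad and occupancy profiles are normalized so the
per-chromosome mean is 1, which makes thresholds and track comparisons
density-independent.

Fragment midpoints of even-length fragments round *down*. The rule is
arbitrary (a double-stranded interval has no strand), and floor is
deterministic; the retained size window 44–58 bp means at most a 0.5-bp
systematic effect, far below the 10-bp rotational spacing of interest.

## The synthetic generator: what it emulates and what it does not

`synthetic_config()` fixes the study conditions; the defaults are not
tuning knobs:

* nucleosome length 147 bp (odd, so the dyad is a single bp);
* linkers drawn i.i.d. from {5, 15, 25} bp with equal weights — the
  quantized linker rule *L = 10n + 5*;
* a 51-bp intranucleosomal core and a 4-bp gap lost at each cut, which
  reproduce the cleavage-site geometry: with `c = 25` the left cut ends
  the upstream piece at `d − 30` and starts the downstream piece at
  `d − 25`;
* per-site cut probability 0.8 and a 5% uniform background (free
  phenanthroline cutting anywhere), so short, medium, and long classes
  all appear at realistic proportions;
* one promoter NDR per gene, a dyad-exclusion interval of width drawn
  from 100–160 bp centered 80 bp upstream of the TSS;
* 60 cells of a 200-kb chromosome with 99 tandem genes every 2 kb,
  about 1.1 × 10^5 fragments — enough that modal structure dominates
  sampling noise while a full run stays around one second.

Arrays are tiled *outward* from the NDR anchors: the −1 and +1 dyads sit
flush against the exclusion zone (the statistical-positioning picture in
which the barrier, not the sequence, phases the arrays), and the two
walks growing toward each other inside an intergenic segment meet at a
single junction gap of at least one nucleosome length. Consequently every
dyad-to-dyad spacing is 147 + {5, 15, 25} except one unquantized junction
per segment, placed mid-segment, far from the promoters. Gene-free
configurations have no junctions at all; the exact-multiset invariants
(e.g. "with p = 1 every interior fragment is a 51-bp core or a
repeat-minus-59 medium") are checked there, because chromosome-terminal
fragments would break any "exact" claim regardless of tiling.

What the generator does **not** emulate: MNase-like sequence bias,
replication/transcription dynamics, fragment-length jitter of the core
(the retained window 44–58 bp is wider than the generator's exact 51 bp),
and real intergenic architecture (convergent/divergent promoters sharing
NDRs). Passing tests therefore demonstrate that the *analysis* recovers
the structure the generator encodes — cleavage geometry, quantization,
barrier parameters — not that real chromatin satisfies these idealized
conditions.

## Dyads, occupancy, and the 2D matrix

Midpoints of 44–58-bp fragments give the dyad profile; occupancy extends
each dyad ±50 bp (101-bp footprints — deliberately smaller than 147 bp so
that alternative positions in different cells leave visible linkers). The
2D occupancy matrix indexes relative coverage by (fragment length ×
position); its column sums are the 1D occupancy and its row sums, divided
by the row's length, are the fragment length histogram. These identities
are exact for integer counts and are asserted in the tests. The
"relative occupancy" normalization divides by (number of anchors ×
mean occupancy), a choice we document in the function because no formula
is standard.

## NDR detection and ±1 refinement

NDRs are the widest maximal run of occupancy below θ × chromosomal mean
(θ = 0.4, minimum 50 bp) inside a transcription-oriented promoter window
(TSS−500 to TSS+150). No published procedure fixes these constants; all
are parameters. Two widths are reported — the sub-threshold run length
and the distance between half-maximum crossings adjacent to the flanking
maxima — because "NDR width" is used in both senses in the field.

Provisional −1/+1 dyads are the first local occupancy maxima flanking the
run, located on a 51-bp moving average: on raw profiles, single-read
background bumps sitting on a 101-bp occupancy plateau displace the
"first local maximum" by up to ±50 bp, which would defeat the refinement
step whose search window is fixed at ±25 bp. Refinement maximizes the
inner product of raw dyad counts with the oscillatory template

D0(x) = G(x,0,2) + 0.75 G(x,±10,2) + 0.50 G(x,±20,2) + 0.25 G(x,±30,2),

G(x,c,σ) = exp(−(x−c)²/2σ²), over candidate centers within ±25 bp. The
template encodes the cluster of alternative *rotational* positions 10 bp
apart that a nucleosome occupies across cells; its decaying weights make
the cluster center, not a satellite, the argmax. Ties break toward the
smallest shift, then the lower coordinate. No variance normalization is
applied — the score is a plain cross-correlation of counts with the
template.

## Gap and NRL estimation

The gap is estimated by cross-correlating genome-wide per-bp counts of
short-class right ends against medium-class left ends over lags 1–20; two
abutting fragments separated by a g-bp lost gap have ends g+1 bp apart,
so gap = argmax lag − 1. Note one source text ambiguity: the medium class
is defined as 70–130 bp in the figure but 130–170 bp in one
cross-correlation paragraph; we classify with (70, 130) and expose the
correlation partner class as a parameter.

The NRL spectrum histograms long-class (135–175 bp) lengths, smooths with
a centered 3-bp moving average, and reports local maxima as modes, with
two numerical choices. First, a mode must reach 10% of the tallest
smoothed peak (`min_prominence`) — with a 5% uniform background, isolated
1–10-count bumps otherwise qualify as "local maxima", which a mode list
of *most abundant* lengths clearly should not include. Second, the
smoothed maximum only localizes a mode to within its 3-bin support
(adjacent noise counts shift the smoothed argmax by ±1 bp), so the
reported mode is the most abundant raw length within that support.
Modal NRL = modal length + gap; linker = NRL − 147. Under the
generator's defaults the spacings are {152, 162, 172}, so the long modes
sit at {148, 158, 168} and the smallest modal NRL is 152; with a 146-bp
core convention the same data would read as linkers {5, 15, 25} against
repeat lengths one bp smaller.

Per-gene spacing assigns long fragments to the gene body containing their
midpoint (midpoint assignment is our choice; full-overlap assignment
differs only at gene edges) and scores each gene by the mean long-fragment
length — a direct measure of average nucleosome spacing. Quintile
summaries rank genes by this score ascending (quintile 1 = most crowded),
distribute remainders to earlier quintiles, and average dyad profiles
aligned at the +1 dyad plus any supplied tracks over the gene-body
(D−73, D+750) and promoter (D−500, D−73) windows.

## Rotational phasing

WW (AA/AT/TA/TT) and SS (CC/CG/GC/GG) dinucleotide frequencies are
averaged over count-weighted dyads; the dinucleotide at offset x spans
bases (dyad+x, dyad+x+1) — a convention we fix and document because either
endpoint could carry the label. Both classes are closed under reverse
complement, so the analysis is strand-symmetric. The generator embeds the
corresponding signal by modulating P(A/T) with amplitude 0.2 times a
10-bp cosine of distance to the nearest pooled dyads; the analysis
recovers a period-10 autocorrelation peak in the WW profile.

## The hard-rod (Tonks) positioning model

Nucleosomes are hard rods of a = 147 bp on a 1D lattice of L bp; a rod
with dyad at k costs binding energy u(k) (in kT, β = 1) against chemical
potential μ; overlap is forbidden, and no other interaction exists. The
grand-canonical partition function obeys the forward recursion
F(i) = F(i−1) + w(i−h) F(i−a), w(k) = exp(μ − u(k)), h = (a−1)/2, with
the mirror-image backward recursion B; Z = F(L),
n(k) = w(k) F(k−h−1) B(k+h+1)/Z, and Occ(i) = Σ_{k=i−73}^{i+73} n(k).
The recursions run in the log domain (Rcpp), which is stable for
lattices beyond 10^6 bp; a pure-R brute-force enumerator over all
non-overlapping configurations (L ≤ 30) is kept as an independent oracle
and agrees to 10^−10 relative on random instances. Only u − μ is
identifiable from n and Occ, so the model is parameterized by u − μ with
μ = 0.

Promoter barriers add to the baseline u − μ two half-Gaussians of height
H and width σ whose centers sit x0 bp *inside* the called −1/+1 dyads,
joined by a flat top at H; overlapping barriers combine by pointwise
maximum, and a promoter whose centers cross (very narrow NDR) degrades
gracefully to the pointwise maximum of the two half-Gaussians. The
barrier is anchored in genomic (not transcription) orientation since it
is mirror-symmetric.

One caveat discovered while testing: occupancy at the barrier center is
*not* strictly monotone in H. For weak barriers (H ≲ 3 kT at
u − μ = −2.5) repacking of the flanking arrays can raise center coverage
by a few tenths of a percent before the barrier term dominates; the
monotonicity property test therefore runs in the barrier-dominated
regime.

## Fitting the barrier

`fit_barrier()` maximizes the Pearson correlation between the flattened
+1-aligned heatmaps (window −400 to +1000 bp) of observed and predicted
dyad densities over (H, σ, x0, u − μ) within a priori bounds H ∈ [1, 15]
kT, σ ∈ [5, 60] bp, x0 ∈ [20, 120] bp, u − μ ∈ [−6, 0] kT. The search is
a seeded Latin-hypercube multistart with a coarse-to-fine Nelder-Mead
schedule: the top 8 of 40 starts get a short refinement, the best 3
refined candidates a full one, and the incumbent is polished by seeded
basin-hopping restarts. The schedule matters: the objective has a decoy
ridge where a saturated H with compensating (σ, x0) reaches 2D
correlation ≈ 0.999, and plain top-k-by-raw-value refinement can land
there; screening more starts cheaply reaches the true basin (correlation
1 at self-consistency). Any global optimizer with a seed and a budget
satisfying the parameter-recovery test is interchangeable here.

The parameter-recovery experiment forward-simulates n(k) on a
200-promoter lattice (2-kb spacing, 280-bp flank span, ~4 × 10^5 bp) at
the reference barrier parameters H = 7.88 kT, σ = 27.64 bp, x0 = 68 bp,
u − μ = −2.79 kT, then refits from random initializations. Across
optimizer seeds the recovered parameters match the truth to well within
10% (H, σ, u − μ) and ±5 bp (x0); with exact forward data the optimum is
the truth itself, so this validates the optimizer and the
objective's identifiability, not measurement noise robustness.

## Problem sizes and determinism

Default problem sizes — 200-kb genome, 60 cells, ~10^5 fragments for the
fragment-level analyses; 4 × 10^5-bp lattice and ~3 × 10^3 objective
evaluations for the fit — were chosen so the modal structure and the fit
are far above sampling noise while a complete run of the test suite and
the reproduction script stays within minutes. Every stochastic stage
(generator, optimizer) takes an explicit integer seed, and the pipeline
derives stage seeds deterministically from one top-level seed; identical
config + seed reproduces byte-identical tables.

## Known limitations

* The NDR caller is a threshold-run heuristic with exposed constants,
  not a reimplementation of any published caller; on real data θ and the
  promoter window will need tuning against the organism's promoter
  architecture.
* The generator's junction gaps slightly contaminate the spacing
  distribution away from promoters; per-gene statistics restricted to
  gene bodies are unaffected.
* The model neglects sequence-dependent affinity by design, remodeler
  and transcription dynamics (non-equilibrium), partial unwrapping, and
  barriers at non-promoter NDRs (tRNA genes, replication origins).
* The fit aligns heatmaps at the +1 dyads of the training set; with few
  promoters (< ~50) the 2D correlation becomes insensitive to x0 on the
  decoy ridge described above.
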