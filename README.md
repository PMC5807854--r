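# nuclinker

Analysis of intranucleosomal chemical-cleavage nucleosome mapping: an
engineered cysteine-phenanthroline histone cuts nucleosomal DNA at two
fixed sites flanking each dyad, so a fragment cut at both sites of one
nucleosome is a ~51-bp core whose midpoint is that *single* nucleosome's
dyad, and fragments spanning neighbouring nucleosomes carry the
dyad-to-dyad distance. The package is written for chromatin researchers
who want to go from paired-end fragment intervals to base-pair-resolution
nucleosome biology:

* **dyad and occupancy maps** — midpoints of 44–58-bp fragments, 101-bp
  symmetric footprints, per-chromosome mean-1 normalization, bedGraph and
  wiggle tracks;
* **2D occupancy** — the (fragment length × position) matrix whose column
  sums are the 1D occupancy and row sums the length histogram, V-plots of
  fragment ends, anchor-aligned sorted heatmaps;
* **promoter architecture** — NDR detection by sub-threshold occupancy
  runs, refinement of the −1/+1 dyads by cross-correlation with the
  oscillatory rotational-position template
  `D0(x) = Σ_k w_k G(x, 10k, 2)`, `w = (1, 0.75, 0.5, 0.25)`;
* **linker quantization** — the bp lost at each cleavage site from the
  lag maximizing the cross-correlation of fragment-end counts
  (gap = lag − 1), modal nucleosome repeat lengths
  NRL = long-fragment mode + gap, linker = NRL − 147, per-gene spacing
  scores and quintile summaries;
* **rotational phasing** — WW/SS dinucleotide frequencies around every
  mapped dyad, A/T content around gene ends;
* **statistical positioning** — a Tonks hard-rod lattice model
  (a = 147 bp) with exact recursive grand-canonical partition function
  `F(i) = F(i−1) + e^{μ−u(i−73)} F(i−a)`, dyad probabilities
  `n(k) = w(k) F(k−74) B(k+74)/Z`, occupancy
  `Occ(i) = Σ_{k=i−73}^{i+73} n(k)`, half-Gaussian promoter energy
  barriers (height H, width σ, centers x0 bp inside the ±1 dyads, flat
  top between), and a seeded global fit of (H, σ, x0, u − μ) maximizing
  the 2D correlation of +1-aligned observed vs predicted dyad heatmaps;
* **a synthetic generator** of the whole experiment (per-cell quantized
  arrays, Bernoulli cleavage, 4-bp lost gaps, background), so every stage
  is testable without sequencing data.

## Worked example

The numbered scripts under `analysis/` run the full study on simulated
data and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_map_dyads.R
Rscript analysis/03_promoters.R
Rscript analysis/04_linker_quantization.R
Rscript analysis/05_rotational_phasing.R
Rscript analysis/06_tonks_model.R
```

`01` simulates 60 cells of a 200-kb chromosome with 99 genes and prints

```
simulated 111882 fragments (60 cells, 99 genes)
fragment classes: short=44672, medium=37085, long=15274, other=14851
```

— the short class are single-nucleosome cores, mediums and longs span
neighbouring nucleosomes. `03` detects an NDR in all 99 promoters and
shows the phased array (dyad peaks at 0, 152, 162, 172 bp from the +1
dyad). `04` prints the central linker-quantization result:

```
end cross-correlation peaks at lag 5 bp -> 4 bp lost per cleavage
modal long-fragment lengths: 148, 158, 168
modal NRLs (mode + gap): 152, 162, 172 -> linkers 5, 15, 25 bp
```

i.e. repeat lengths recover the generator's quantized linker mixture
147 + {5, 15, 25}, separated by the ~10-bp helical twist. `05` shows the
rotational signal (WW frequency 0.455 at the dyad vs 0.270 genome-wide;
WW autocorrelation peak at lag 10, r = 0.94). `06` forward-simulates dyad
densities on a 200-promoter lattice at reference barrier parameters and
refits them from random starts:

```
truth     : H=7.88 kT sigma=27.64 bp x0=68 bp u-mu=-2.79 kT
recovered : H=7.88 kT sigma=27.64 bp x0=68.0 bp u-mu=-2.79 kT
2D correlation at the optimum: 1.000000
```

with predicted occupancy 0.098 inside a promoter barrier versus 0.965 in
the flanking arrays — steric exclusion against promoter barriers alone
generates NDRs and phased arrays.

`run_pipeline()` exposes the same stages as one call on a YAML/list
config (synthetic or file input) with a single top-level seed and a run
manifest; identical config + seed reproduces byte-identical tables.

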