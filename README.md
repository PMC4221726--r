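# tsbf — transformed sliding band filter for bright-field cell counting

`tsbf` detects and counts cultured cells in **bright-field** micrographs,
where an unstained cell appears as a dark membrane ring on a mid-gray
background rather than as a bright blob. It is aimed at routine culture
density checks — e.g. monitoring Sf9 insect-cell suspensions during
baculovirus expression work — where cells are counted per hemocytometer
square and converted to cells/mL, and where classical blob detectors
(Laplacian of Gaussian, intensity thresholding) fail on the ring
morphology.

## The method

All detectors in the convergence-index (CI) family score a candidate
center from the gradient field along `N` radial support lines. The plain
CI is the mean cosine of the angle between each support pixel's gradient
and the direction from that pixel toward the center; the sliding band
filter (SBF) restricts support to a band of `Bw` consecutive radii that
slides in `[Rmin, Rmax]` independently per line (each line contributes its
best band):

    SBF(x,y) = (1/N) Σ_i  max_{r ∈ [Rmin, Rmax]} (1/Bw) Σ_b cos α(φ_i, r+b)

A bright-field membrane ring defeats signed convergence: gradients
converge just *inside* the membrane and diverge just *outside* it. The
transformed SBF (TSBF) replaces the per-sample cosine with

    ω · |cos α| · ‖∇I‖

so both membrane edges reinforce the center response and the score
concentrates on the membrane, where the gradient evidence lives. Cell
centers are the local maxima of the TSBF map under non-maximum
suppression ((n+1)×(n+1) window, strict domination, lexicographic
plateau tie-break). Defaults: `Rmin = 8`, `Rmax = 30`, `N = 32`,
`Bw = 6`, `ω = 1`, NMS window side 17, threshold mean + 2·sd of the map.

Counting accuracy is reported as the relative error per density,
`ERT = |N − G| / G`, and its mean over sampled densities (`TERT`);
densities follow the standard chamber formula
`cells/mL = count × dilution × 10^4` for 1 mm² squares at 0.1 mm depth.

Because no public ground-truth bright-field dataset exists, the package
ships a synthetic scene generator with planted truth (dark annulus cells
with blur, noise and optional illumination ramp; dark-field Gaussian-blob
scenes for the classical case) and a standing benchmark: 15 bright-field
256×256 scenes, 10–20 non-overlapping cells each, radii 10–22 px,
seed 42.

## Worked example

```r
library(tsbf)
sc  <- generate_brightfield_scene(scene_spec(n_cells = 6, seed = 7))
det <- detect_cells(sc$image)   # TSBF map + non-maximum suppression
det
#> TSBF detection: 6 centers (threshold 0.02203)
#>  row col   score border
#>   95 224 0.04014   TRUE
#>  189  37 0.03962  FALSE
#>  239  87 0.03935   TRUE
#>  117  35 0.03908  FALSE
#>   55  71 0.03860  FALSE
#>   56 117 0.03841  FALSE
match_centers(det, sc, tolerance = 5)[c("tp", "fp", "fn")]
#> $tp [1] 6   $fp [1] 0   $fn [1] 0
cells_per_ml(det$count)
#> [1] 60000
```

All six planted cells are recovered, each within 5 px of its planted
center (coordinates are 0-based `(row, col)`; `border` flags centers
inside the clipped-support margin, `score` is the TSBF response). If the
frame were a chamber square, 6 cells correspond to 6 × 10⁴ = 60,000
cells/mL.

A command-line wrapper with `detect`, `synth`, `eval` and `bench`
subcommands is installed at
`system.file("cli", "tsbf.R", package = "tsbf")`:

```sh
Rscript tsbf.R synth  --images 15 --size 256 --seed 42 --out scenes/
Rscript tsbf.R detect --input 'scenes/*.tif' --rmin 8 --rmax 30 --out det/
Rscript tsbf.R bench  --seed 42 --out bench_out/     # synth → detect → eval
```

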