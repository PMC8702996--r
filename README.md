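# chromphasor

Phasor FLIM-FRET analysis of chromatin compaction around DNA double-strand
breaks.

## What this package is for

FRET between donor- and acceptor-tagged histones (H2B-eGFP / H2B-mCherry)
reports nucleosome proximity — chromatin compaction — with nanometre
sensitivity, and fluorescence lifetime imaging (FLIM) maps it per pixel
across an intact nucleus. `chromphasor` is for microscopists and DNA-repair
biologists who acquire such data (e.g. in DSB-inducible cell systems
alongside immunofluorescence of γH2AX, 53BP1 or BRCA1 foci) and need the
full analysis chain as reproducible, scriptable code:

1. **Phasor transform** of per-pixel photon-count decay stacks:
   `g = Σ C_b cos(ω t_b)/Σ C_b`, `s = Σ C_b sin(ω t_b)/Σ C_b`, with
   `ω = 2π/T` at the laser repetition period `T`. Single-exponential decays
   land on the universal semicircle at
   `g = 1/(1+(ωτ)²)`, `s = ωτ/(1+(ωτ)²)`.
2. **Calibration** against a reference dye of known lifetime (fluorescein
   at pH 9, 4.04 ns) by complex division — one global phase/modulation
   correction.
3. **FRET trajectory and cursor palette**: the donor quenched at
   efficiency `E` has lifetime `τ_D(1−E)`; with the 2.5 ns H2B-eGFP donor
   and the compact state at `E = 1 − 2.1/2.5 = 16%`, the open and compact
   cursors sit at (0.39, 0.49) and (0.47, 0.50) (radius 0.05) at 80 MHz.
4. **Reciprocal-mode classification** of pixels into open / compact /
   unclassified, and the compact-pixel fraction per nucleus.
5. **IF-guided mask analysis**: 3×3 median filter, threshold mask
   (Otsu or absolute, realized value logged), compact fraction inside vs
   outside DSB foci, and the nucleoplasm-normalized ratio.
6. **Particle analysis** of compact-chromatin foci: 8-connected labeling
   with hole filling, areas in µm², pooled size histograms.
7. **Cohort statistics**: per-condition min/median/max summaries, unpaired
   and paired t-tests.
8. A **synthetic FLIM-nucleus simulator** (Poisson photon statistics,
   wrapped-exponential decays, DSB/IF/acceptor channels, full ground truth)
   so every stage is testable without instrument data.

## Worked example

Simulate a DSB-bearing nucleus under the default study conditions
(256×256 px at 90 nm/pixel, 80 MHz/256 bins, 800 photons/pixel, 30%
compact chromatin, 100 DSB foci forced open) and analyze it end to end:

```r
library(chromphasor)

meta <- flim_meta()                      # 80 MHz, 256 bins, 90 nm/pixel
single_exponential_phasor(c(2.5, 2.1), meta)
#> # A tibble: 2 × 2
#>       g     s
#>   <dbl> <dbl>
#> 1 0.388 0.487
#> 2 0.473 0.499

cell <- simulate_cell(flim_sim_config(seed = 42))
ca <- analyze_cell(cell$donor, cell$acceptor, cell$if_channel,
                   cell_id = "demo", condition = "4OHT_2h", channel = "gH2AX")
ca
#> <cell_analysis> demo: fraction_compact = 0.316, inside/outside = 0.037/0.370,
#>   683 compact particles
```

The numbers mean: 31.6% of classified nucleus pixels are in the compact
(FRET) cursor, against a simulated ground truth of 30.0%; inside the
IF-segmented DSB foci only 3.7% of pixels are compact versus 37.0% in the
surrounding nucleoplasm (normalized inside fraction 0.10), i.e. DSB sites
read as strongly "open"; and the compact pixels decompose into 683
particles with a median area of 0.0081 µm² (one 90 nm pixel).

Everything downstream is a tibble and pipes:

```r
library(dplyr)
report <- simulate_cohort(n_per_condition = 5) |> run_pipeline()
tidy(report)            # per-cell records
glance(report)          # cohort overview with headline p-values
report$tests            # unpaired condition test, paired inside/outside test
autoplot(ca$phasor, palette = default_palette(),
         trajectory = build_fret_trajectory())   # phasor plot
autoplot(ca$classification)                      # teal/red/black FLIM map
```

A thin CLI wraps the same functions
(`inst/cli/chromphasor.R simulate|phasor|run`); see `--help`-style usage at
the top of that file.

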