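# focimetry

Automated scoring of DNA double-strand-break (DSB) repair foci in
fluorescence-microscopy images.

DSBs are visualized by immunofluorescence as nuclear foci of γH2AX and
53BP1. Counting them per nucleus measures DSB repair, but at low radiation
doses (tens of mGy) only fractions of a focus per cell are induced, so
reliable numbers require thousands of nuclei — and unspecific staining
artifacts outnumber genuine foci 10–20:1. `focimetry` automates the chain:
nucleus segmentation and single-cell cropping from DAPI, best z-plane
selection per marker, object detection by local-maximum seeding and area
growing, a composite per-object score, and histogram-valley thresholding
with an optional rater-in-the-loop refinement.

The score at the core is the object evaluation parameter (OEP). Per channel,

    OEP_red/green = (I_TH / I_nucl) · I_LC · C

where `I_TH` and `I_LC` are the means of the three brightest object pixels
in the top-hat and Laplacian-of-Gaussian transformed images, `I_nucl` is
the mean nucleus intensity, and `C = 1 / Σ r²I` is the object's compactness
(inverse intensity-weighted moment of inertia). The two channels combine
with a per-cell weight `w = sd_red / sd_green`:

    OEP = OEP_red^w · OEP_green^(1/w)

On the log scale the OEP distribution of a sample is bimodal — background
signals left, foci right — and the valley is the detection threshold.
Foci per cell is the number of above-threshold objects divided by the
number of analyzed (G1-gated) cells.

## Worked example

Simulate a field with known ground truth, run the pipeline, and count foci:

```r
library(focimetry)

sim <- synth_field(synth_spec(rng_seed = 1))   # 1024 x 1360 px, ~50 nuclei
run <- run_pipeline(sim$field)
run
#> <foci_run> 40 analyzed cells, 300 objects; foci/cell = 0.825
#> <quality_check> PASS | mean Pearson 0.429

glance(run)
#> # A tibble: 1 × 6
#>   n_cells n_objects threshold foci_per_cell mean_pearson verdict
#>     <int>     <int>     <dbl>         <dbl>        <dbl> <chr>
#> 1      40       300      9.28         0.825        0.429 ok
```

Forty of the fifty nuclei survive border cropping and the G1 gate; the
pipeline detects ~7.5 objects per cell (mostly background speckles), places
the threshold at the valley of the log-OEP histogram, and the resulting
0.825 foci per cell estimates the simulation's planted rate of 1 focus per
cell from this single field. `autoplot(oep_histogram(run$objects$oep, "log"))` shows the bimodal
histogram with the smoothed curve used for valley finding.

Downstream, repair efficiency after a dose is the persisting fraction of
the foci initially induced (20 foci per cell per gray):

```r
repair_efficiency(irradiated_fpc = 1.30, control_fpc = 0.30, dose_gy = 1)
#> # A tibble: 1 × 5
#>   dose_gy induced persisting persisting_fraction nonpositive
#>     <dbl>   <dbl>      <dbl>               <dbl> <lgl>
#> 1       1      20          1                   5 FALSE
```

A thin command-line front end with `simulate`, `crop`, `score`,
`threshold` and `report` subcommands is installed at
`inst/cli/focimetry.R`.

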