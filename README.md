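# sarsense

How many tissues does a pelvic model need before predicted radiofrequency
hyperthermia dose stops changing? `sarsense` answers this question at desk
scale for researchers in hyperthermia treatment planning and computational
dosimetry: it generates synthetic-but-structured pelvic voxel phantoms,
solves the 100 MHz electromagnetic problem of a 12-channel annular phased
array around a water bolus, optimizes the per-channel drive, and compares
detailed against reduced tissue segmentations with the field's standard
dose metrics.

## The dose model

With peak field phasor **E**, conductivity σ and density ρ,

    SAR = σ ||E||² / (2ρ)                     [W/kg]

Treatment quality is the target-to-hotspot quotient

    THQ = mean SAR(HTV) / mean SAR(V1%)

where V1% is the hottest 1 % of healthy tissue outside the hyperthermia
target volume (HTV). Segmentation impact is quantified against the
detailed benchmark as absolute relative differences, in percent:

    |dTHQ|   = |(THQ_n − THQ_ref) / THQ_ref| · 100
    |dRD|_t  = |(M_n,t − M_ref,t) / M_ref,t| · 100

with `M` the mean SAR over the hottest 1 % of tissue *t*. Cells with
max |dTHQ| ≤ 5 % are flagged below clinical relevance (≈ 0.2 °C in median
target temperature, applied as a cited constant); |dRD| is judged against
a 0–20 % band.

The drive that maximizes THQ on the detailed benchmark — found by a
global-best particle swarm over per-channel amplitudes and phases — is
frozen and re-applied to every reduced segmentation, whose fields are
re-solved on the same grid; the metric differences therefore isolate the
segmentation effect alone.

## Worked example

```r
library(sarsense)

params  <- phantom_params(tumor_site = "cervix", fat_fraction = 0.35)
phantom <- generate_phantom(params, seed = 42)
phantom
#> <voxel_phantom> 66 x 44 x 80 @ 5 mm
#>   site: cervix (female), GTV size: medium
#>   GTV voxels: 48, HTV voxels: 340

vs <- compute_volume_stats(phantom)
sprintf("fat %.1f%%, muscle %.1f%%, bone %.1f%%",
        vs$fat_pct, vs$muscle_pct, vs$bone_pct)
#> "fat 35.1%, muscle 56.8%, bone 5.5%"

cfg <- experiment_config(
  phantom = params, sites = "cervix", sizes = c("small", "medium", "large"),
  schemes = c("detailed", "clinical", "bladder", "intestine"),
  drive = "focus", seed = 42)
run_study(cfg)
#> <study_report> 12 cells, 0 failures
#> max |dTHQ| across sizes, by scheme:
#>  phantom   site    scheme max_dthq_pct sd_dthq_pct dthq_acceptable
#>        1 cervix   bladder     2.520635   0.9120773            TRUE
#>        1 cervix  clinical    12.628467   0.9189487           FALSE
#>        1 cervix  detailed     0.000000   0.0000000            TRUE
#>        1 cervix intestine     5.282021   0.1512064           FALSE
```

Reading the output: merging everything into the four clinical classes
shifts the predicted THQ by up to 12.6 % across the three tumor sizes —
well past the 5 % relevance threshold — while additionally delineating
the bladder (urine at 1.75 S/m vs muscle at 0.708 S/m) brings the model
within 2.5 % of the detailed benchmark for this phantom. `sd_dthq_pct` is
the spread of |dTHQ| across the three GTV sizes, reported alongside the
maximum. A full report also carries per-tissue |dRD| tables and boxplot
summaries (`write_study_report()` emits CSV/JSON).

A command-line front end with `phantom`, `solve`, `optimize`, `dose` and
`study` subcommands lives at `inst/cli/sarsense.R`; all subcommands take
`--config <yaml>` and `--seed`.

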