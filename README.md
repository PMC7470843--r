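# spbquant

Quantitation of spindle pole body (SPB) structural asymmetry from
dual-channel 3D fluorescence stacks of budding yeast, together with a
ground-truthed synthetic image generator that makes the entire analysis
chain testable without microscope data.

## What it measures, and for whom

The yeast SPB is a layered organelle: an inner plaque (IP) nucleates
spindle microtubules in the nucleus, an outer plaque (OP) nucleates astral
microtubules in the cytoplasm, and a bridge joins the two SPBs of a
duplicating pair. SPB duplication is conservative, so every cell has an
*old* and a *new* SPB, and several components (γ-tubulin complex, Spc72)
distribute unequally between them at scales of 150–350 nm — at the edge of
what super-resolution (SIM-class) imaging resolves. This package is for
cell biologists and microscopists who need the standard quantitation chain
for such data:

* one- and two-component **3D Gaussian spot fitting** (axially
  anisotropic, shared background, amplitudes = integrated photons);
* **screening rules**: exclusion of SPBs peaking in the first/last z-slice
  and of "top view" SPBs whose plaques overlap laterally;
* **realignment** of each image along the inter-SPB (or IP–OP) axis with
  the old SPB (brighter reference spot) on the left, then **class
  averaging** and display scaling (4×4 bilinear, 8-bit);
* **linescan profiles** (1/3/5-px width, min–max or reference
  normalization) with plaque-peak role assignment;
* **metrics**: the asymmetry index, IP:OP ratio, fold-change mode classes,
  spindle-length staging, and boxplot centile/notch summaries;
* a lower-resolution **wide-field path**: maximum projection, 7×7-px
  integrated intensities with cell-background subtraction, and
  reference-normalized asymmetry.

## The core quantities

For label intensities $a, b$ at the two SPBs of one spindle (optionally
normalized by a reference label, $a = I_\text{query}/I_\text{ref}$):

$$\mathrm{AI} = \frac{|a-b|}{a+b} \in [0,1], \qquad
  \mathrm{IP{:}OP} = \frac{I_\mathrm{IP}}{I_\mathrm{OP}}$$

with AI = 0 for perfect symmetry and 1 when one pole carries all the
label. Spindles are classified by the fold-ratio $r = \max(a,b)/\min(a,b)$:
**one pole** (dimmer pole below the detection floor), **strongly
asymmetric** ($r \ge 8$), **asymmetric** ($1.3 \le r < 8$), **symmetric**
($r < 1.3$); and staged by SPB inter-distance $d$: unseparated
($d < 0.35$ µm), short spindle ($0.35 \le d < 1$), spindle
($1 \le d \le 2.5$), elongated ($d > 2.5$).

## Worked example

Generate a population of 30 short spindles whose outer-plaque label is
10-fold brighter at the old SPB, run the full pipeline, and recover the
asymmetry:

```r
library(spbquant)
out <- run_pipeline(run_config(
  n = 30, stage_mix = c(short_spindle_lt1 = 1),
  asymmetry = asymmetry_config(op_fold = 10, ip_op_ratio = 0),
  seed = 303))
median(out$results$asymmetry_index)
table(out$results$mode)
```

Running `analysis/03_asymmetry_modes.R` (which sweeps folds 1, 2, 5, 10
with these settings) prints:

```
 fold  n expected_index median_index    p25    p75
    1 30          0.000       0.0207 0.0121 0.0316
    2 30          0.333       0.3288 0.3091 0.3464
    5 30          0.667       0.6715 0.6499 0.6930
   10 30          0.818       0.8305 0.7858 0.8486
```

so the median recovered index tracks the generated truth
$(f-1)/(f+1)$ across the sweep, and at fold 10 the mode table is
dominated by `strongly_asymmetric` (24/30, the rest `asymmetric` —
per-spindle fold estimates scatter around 10, so some fall below the
$r \ge 8$ boundary). `analysis/04_ip_op_ploidy.R` recovers a generated
IP:OP ratio of 2.5 as 2.507 (haploid, n = 40) and 2.488 (diploid), with
diploid:haploid intensity ratios of 1.997 (IP) and 2.011 (OP) against the
expected gene-dose factor 2.

## Analysis workflow

The `analysis/` directory holds numbered drivers over the package, each
writing its tables under `results/`:

1. `01_simulate.R` — simulate a mixed asynchronous population, archive
   example TIFF stacks with ground-truth sidecars;
2. `02_fit_and_stage.R` — fit, screen, realign and stage the population;
3. `03_asymmetry_modes.R` — fold sweep, index recovery, mode counts;
4. `04_ip_op_ploidy.R` — IP:OP ratio and haploid/diploid scaling;
5. `05_widefield_comparison.R` — wide-field vs SIM concordance on matched
   scenes.

The methods vignette (`vignettes/spb-asymmetry-quantitation.Rmd`) explains
the model, the synthetic generator, and every numerical choice.

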