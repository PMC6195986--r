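# cleftmorph

Quantitative morphometry of congenital secondary-palate clefts
(palatoschisis) in neonatal-dog-scale CT volumes.

A cleft palate is a slit-shaped communication between the oral and nasal
cavities left by failed fusion of the palatal shelves. On neonatal head CT
the bony palate is a thin curved shell, so measuring the defect on a flat
reconstruction under-estimates its surface: the area has to be measured on
a surface that follows the palate's natural curvature. `cleftmorph`
automates that measurement end to end:

1. **Segmentation** — bone mask at the inclusive Hounsfield-unit cut-off
   `HU >= 140`, largest connected component.
2. **Surface extraction** — marching-tetrahedra iso-surface of the
   segmentation (Gaussian pre-smoothing of the threshold indicator +
   shrink-compensated Taubin mesh smoothing suppress voxelisation
   staircase bias), exportable as STL.
3. **Palate isolation** — optional ROI cropping, then extraction of the
   oral (ventral) surface sheet by face-normal orientation.
4. **Defect detection** — boundary loops of the oral sheet; gaps narrower
   than `min_gap_mm` (default 1 mm) are *bridged* as normal unfused
   sutures, true cleft outlines are snapped onto the locally fitted bone
   walls.
5. **Virtual filling** — a tensor-product B-spline (NURBS with unit
   weights) patch is fitted by penalized least squares to the palate
   around each outline, iterated with closest-point re-parameterization,
   tessellated, and trimmed to the defect outline.
6. **Morphometry** — cleft surface area `A_c`, total hard-palate area
   `A_p` (residual oral sheet + fills), the integer percentage
   `round(100 * A_c / A_p)`, defect length and transverse width range,
   plus the four-region numerical cleft classification code
   (lip–alveolus–hard–soft, right/left grades 0–3, e.g. `03-01-00-00`).

Every stage is testable without clinical scans through a built-in phantom
generator: a parabolic-cylinder bone shell `z = a x^2` of known thickness
with polygonal cleft outlines, sub-millimetre suture slits and optional
noise, whose true curved areas `∬ sqrt(1 + 4 a^2 x^2) dx dy` come from an
independent quadrature oracle.

## Worked example

```r
library(cleftmorph)

# a curved palate shell with one 5 mm midline cleft, voxelised at 0.5 mm
spec <- standard_suite()$curved_midline_5mm
ph   <- generate_phantom(spec)

meas <- run_pipeline(ph$volume, animal_id = "phantom_01")
meas[, c("animal_id", "total_area_mm2", "cleft_area_mm2", "percentage",
         "length_mm", "width_min_mm", "width_max_mm", "n_loops")]
#> # A tibble: 1 x 8
#>   animal_id  total_area_mm2 cleft_area_mm2 percentage length_mm width_min_mm width_max_mm n_loops
#>   <chr>               <dbl>          <dbl>      <int>     <dbl>        <dbl>        <dbl>   <int>
#> 1 phantom_01           507.           81.8         16      16.1         4.92         4.97       1

sum(ph$truth$cleft_area_true)   # 80.07 mm^2 analytic truth -> ~2% recovery error
ph$truth$percentage_true        # 16
```

The measured cleft area (81.8 mm²) is the trimmed spline fill; the total
(507 mm²) is the residual oral sheet plus that fill, so the percentage is
well defined even for wide defects. The classification codec round-trips
printed codes, including mixed dashes and midline forms:

```r
encode_cleft_code(parse_cleft_code("00–00–3-3"))
#> [1] "00-00-3-3"
```

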