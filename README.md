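# mritexture

Objective, texture-based quality comparison of grayscale MR images.

Radiologists comparing 1.5 T and 3 T acquisitions of the same anatomy —
fetal brain being the motivating case — usually cannot tell them apart by
eye, and DICOM headers routinely overstate how much dynamic range an
image really holds. `mritexture` is for imaging scientists who want that
comparison done numerically: it audits the bit depth pixel data actually
occupies, extracts first-order histogram features and Haar wavelet
subband energies per region of interest (ventricles, thalamus, grey
matter, white matter), derives two scalar quality indices, and scores how
well the anatomical regions separate in feature space. A synthetic
labeled brain phantom stands in for patient data, so the entire pipeline
is testable offline.

## The statistics at the core

* **Focus index** `skewness / kurtosis` (excess kurtosis, population
  moments): ~0 for well-focused texture; samples outside `[-1, +1]` are
  treated as noise and filtered out.
* **Dispersion index** `variance / mean` (VMR): larger spread between
  region values means better discriminability.
* **wavenhl**: mean squared HL-subband coefficient of an orthonormal Haar
  transform over the ROI window — a vertical-edge "fingerprint" of each
  region.
* **Feature-selection coefficient**

  `F = D² / V²`, with
  `D² = [1 / (1 − Σ P_k²)] Σ_k Σ_j P_k P_j ‖μ_k − μ_j‖²` and
  `V² = Σ_k P_k V_k²`,

  a between-class to within-class variance ratio over the
  `(dispersion, focus, wavenhl)` space, evaluated together with the
  leave-one-out 1-nearest-neighbour misclassified-data-error (MDE).
  Fixed control points `C_min`/`C_max` bound the space before scoring.
* **Bit audit**: measured usable bits = smallest `b` with
  `max(pixels) ≤ 2^b − 1`; conversion to 8 bits discards least
  significant bits relative to the *measured* depth, never the reported
  one.
* **Group statistics**: best-nine selection per cell and pooled
  (equal-variance) two-sample t-tests, `df = n_a + n_b − 2`.

## Worked example

```r
library(mritexture)

# a 1.5 T-like phantom: 256x256, 12 stored bits zero-padded into 16
ph <- generate_phantom(modality_preset("t1p5", seed = 7))
measure_usable_bits(ph$image)
#> <bit_report> range [0, 3861], span 3862 levels (3293 occupied)
#>   usable bits measured: 12, reported: 12
```

Twelve usable bits despite the 16-bit container: with noise the pixel
values stay below 4095, and the audit reads the depth off the data, not
the header. The control-point worked example — two classes of two points
in `(dispersion, focus, wavenhl)` space, one control displaced to
`(0, -1, 60000)`:

```r
fisher_analysis(control_matrix("t3_perturbed"))
#> <fisher_result> F = 17.8667
#>   D2 (between-class) = 8.10756e+09, V2 (within-class) = 4.53781e+08
#> <nn_result> MDE = 25% (1 of 4 misclassified)
```

F rounds to 18 and exactly one of the four points (the displaced
control, whose nearest neighbour lies in the other class) is
misclassified. The bundled nine-value index columns from the 1.5 T vs
3 T group comparison reproduce the published summary lines:

```r
summary_table(example_grouped_indices())
#>   index_kind age_group modality n         m        sd      t df         p
#> 1      focus        g1     t1p5 9 1.748e-01 8.269e-02  6.287 16 1.082e-05
#> 2      focus        g1       t3 9 1.504e-03 1.052e-03  6.287 16 1.082e-05
#> ...
#> 5 dispersion        g1     t1p5 9 1.415e+02 8.531e+01 -8.513 16 2.453e-07
#> 6 dispersion        g1       t3 9 2.806e+03 9.352e+02 -8.513 16 2.453e-07
```

i.e. means 0.175 vs 0.0015 (focus, group 1) and 142 vs 2806 (dispersion,
group 1), with t(16) = 6.3 and −8.5: the 3 T cells sit closer to ideal
focus and disperse far more strongly.

The same operations are scriptable from a shell:

```sh
exec/mritexture phantom --preset t3 --seed 7 --out out/
exec/mritexture audit out/t3_seed7.dcm
exec/mritexture convert out/t3_seed7.dcm out/t3_seed7.bmp
exec/mritexture fisher --matrix inst/extdata/control_matrix_t3_perturbed.csv
```

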