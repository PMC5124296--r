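# CSV schemas

## feature matrix (`fisher` subcommand input, `read_feature_matrix()`)
- `sample_id` — unique sample identifier
- `class` — class label (region name or `control_min`/`control_max`)
- remaining columns — numeric features; for the 3-D analysis space:
  `dispersion`, `focus`, `wavenhl`

## features (`features` subcommand output)
- `roi_label` — region name
- `n` — pixel count of the ROI
- `mean`, `variance` — population first-order moments (intensity, intensity^2)
- `skewness`, `kurtosis_excess` — dimensionless; `NA` when undefined
- `wavenll`, `wavenlh`, `wavenhl`, `wavenhh` — mean squared Haar subband
  coefficients (intensity^2) at `scale`

## indices (`indices` subcommand output; adds to the features schema)
- `focus_index` — skewness / excess kurtosis
- `dispersion_index` — variance / mean
- `in_focus_range` — TRUE iff focus_index in the closed retention interval
  (exclusions are written to `<out>.excluded.csv`)

## grouped indices (`compare` subcommand input, `example_grouped_indices()`)
- `modality` — `t1p5` or `t3`
- `age_group` — `g1` (20-28 weeks) or `g2` (29-40 weeks)
- `index_kind` — `focus` or `dispersion`
- `value` — index value

## summary (`compare` subcommand output, `summary_table()`)
- `index_kind`, `age_group`, `modality`, `n`
- `m`, `sd` — sample mean and sample (n-1) standard deviation of the cell
- `t`, `df`, `p` — pooled two-sample t (t1p5 minus t3) within the age group
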