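# extdata

`s1_table/` (not shipped): per-subject metric sheets for statistics-only
reproduction runs. The layout expected by `read_metric_sheets()` is one CSV
per metric — `snr.csv`, `endpoints.csv`, `segment_length.csv`,
`density.csv`, `icd.csv`, each with columns `subject, region, n_frames,
value` (regions S, ST, T, IT, I; n_frames 1-10) — plus optionally
`poag_density.csv` (`subject, region, density_mm_inv`) with 10-frame
patient densities for the normative comparison. These sheets are a direct
CSV export of a published supplementary workbook of per-subject values,
which is third-party data and therefore not redistributed here.
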