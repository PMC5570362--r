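# extdata

- `pe_etr_TO03_lowCu_synthetic.csv` — **synthetic** low-Cu ETR PE
  replicate curves (3 replicates x 11 irradiance levels), generated from
  the TO03 low-Cu scenario preset (`gen_pe_dataset("TO03_lowCu", "ETR",
  noise_cv = 0.05, seed = 42, n_rep = 3)`) and stored as plain text so
  the file-based refit pathway (`read_pe_csv()` -> `fit_pe_table()`) is
  exercised from disk. It stands in for raw instrument exports; it is
  not measured data.
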