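# Bundled fixtures

## dose_table_72_locations.csv

Per-location one-year cumulative surface β-ray doses at 72 representative
locations in Fukushima prefecture, digitized from the published assessment
built on the 2011 MEXT 2-km mesh soil contamination survey. Columns:

- `location_id` — place name
- `lat`, `lon` — degrees (WGS84)
- `sample_date` — the table's ratios are uniformly consistent with a single
  decay-correction interval of 91 days after the 2011-03-15 deposition,
  i.e. 2011-06-14; that date is stored for every row
- `i131`, `cs137`, `te129m` — measured deposition densities, kBq/m²
  (`te129m` empty where not measured; its corrected ratio was spatially
  interpolated in the source)
- `r_i`, `r_t` — I-131/Cs-137 and Te-129m/Cs-137 ratios decay-corrected to
  2011-03-15, as printed (2–3 significant figures)
- `d_unit` — dose per 1000 kBq/m² Cs-137, mSv
- `d_a` — absolute dose, mSv

Digitization notes: the source text concatenates the numeric columns;
fields were recovered by exhaustive tokenization constrained by
(a) `d_a = d_unit·cs137/1000` within printed rounding, (b) `d_unit` within
a few per cent of the linear dose surface at the printed ratios, and
(c) the corrected `r_i` being consistent with the raw activities for a
common decay-correction interval (found to be 91 d for every row). Three
rows (Koriyama-Hiwada, Tanakura, Motomiya-Motomiya) print an `r_t` about
2–3× larger than their raw Te-129m/Cs-137 implies at 91 d; printed values
are kept. One row (Kodono Town) admits two near-equivalent readings; the
one matching the 91-d interval best was kept.

## intercept_fit_table.csv

The per-`r_t` intercepts `b` of the least-squares fit
`D = a·r_i + b` of the one-year dose surface, at
`r_t ∈ {0.1, 0.5, 1, 5, 10, 50}`. The last row is digitized from a source
reading of "601.6", which is inconsistent with the fitted line
`b(r_t) = 31.032·r_t + 50.009` (which requires ≈1601.6 at `r_t = 50`);
it is stored as 1601.6. Re-fits should prefer the four unambiguous rows
`r_t ∈ {0.1, 0.5, 1, 5}`.
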