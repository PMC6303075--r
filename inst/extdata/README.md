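# extdata

No data files are shipped here. To run the three acceptance tests that
re-analyse the original raw diallel table, export the raw-data sheet of the
original study's supplementary data workbook as CSV with columns
`fitness, sex, sire, dam, block` (sex coded 1 = female / 2 = male), save it
as `s1_data_raw.csv` in this directory, and reinstall the package.
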