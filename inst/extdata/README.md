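# Example data files

All files here are **synthetic** fixtures written by the package's own
generators; none contain instrument data. They mimic the ASCII layouts of
common electrochemical workstations so the tolerant parser can be exercised
on realistic-looking input:

- `synthetic_chi.txt` — CHI-style export: multi-line text header, then
  `Potential/V, Current/A` data in comma-plus-space delimited columns.
- `synthetic_basi.txt` — BASi-style export: short header block, blank line,
  then comma-delimited columns.
- `synthetic_autolab.ocw.txt` — Autolab-style ASCII `.ocw` export: two
  space-padded numeric columns without a header.
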