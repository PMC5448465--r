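# Example configuration files

- `policy.json` — an illustrative salt-policy configuration: market shares
  and iodine concentrations for manufacturer iodised salt (bread 95% at
  58 mg I/kg bakery salt; pizza 40% with half of its salt attributable to
  added iodised salt; processed meat 0.5%; 20 mg I/kg low-iodine salt
  elsewhere), discretionary added-salt amounts and use shares, and
  never-discretionary-salt-user proportions by age-sex band. The never-user
  proportions and discretionary amounts are synthetic illustrations, not
  survey-measured values.
- `dri.json` — an illustrative dietary-reference-intake table (EARs in the
  style of the IOM iodine values, ULs in the style of the SCF values).
  Supply your own authoritative values for real analyses.

Both files are in the exact format accepted by `read_policy()` and
`read_dri()`.
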