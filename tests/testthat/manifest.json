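{
  "command": "simulate",
  "flags": {
    "arm": "lobectomy"
  },
  "seed": {},
  "package_version": "1.0.0",
  "r_version": "4.3.3",
  "timestamp": "2026-09-29T03:53:04+0000",
  "outputs": ["trace_lobectomy_age45.csv", "trace_lobectomy_age50.csv", "trace_lobectomy_age55.csv", "trace_lobectomy_age60.csv", "trace_lobectomy_age65.csv", "trace_lobectomy_age70.csv", "trace_lobectomy_age75.csv", "trace_lobectomy_age80.csv", "trace_lobectomy_age85.csv", "life_expectancy_lobectomy.json"]
}
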