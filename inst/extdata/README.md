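# Bundled fixtures

The arm-level 52-week outcome data analyzed in the source trials are not
publicly deposited, so these fixtures are reconstructions, flagged row by row
in the `provenance` column:

- `printed` (in `direct_estimates.csv`): contrast-level posterior medians and
  95% credible intervals exactly as published for the base-case network.
- `derived`: arm-level cells constructed so that the trial-level direct
  estimate (difference of arm means; SE from pooled arm variances) reproduces
  a published direct contrast and its interval width. Arm means/SDs
  individually are not published values.
- `synthetic`: plausible values chosen to complete the data model (no
  published counterpart); trial ns and baseline summaries come from the
  published baseline tables where available.

Files: `base_case.csv` (Thornton, Deal, Miller), `sa1.csv` (base +
Khadilkar/LB03002), `sa2.csv` (base + Horikawa), `direct_estimates.csv`
(published base-case contrasts). Schema: see `?read_trials`. Regenerate with
the generator functions (`?make_paper_like_network`) or rebuild the derived
SDs from `direct_estimates.csv` via `?se_from_interval`.
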