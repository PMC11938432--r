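trial_id,week,treatment,outcome,n,baseline_mean,baseline_sd,followup_mean,followup_sd,change_mean,change_sd,events,provenance
thornton2021,52,lonapegsomatropin,ahv,105,,,11.2,2.1892,,,,derived
thornton2021,52,daily_somatropin,ahv,56,,,10.3,2.1892,,,,derived
thornton2021,52,lonapegsomatropin,height_sds,105,-2.89,0.85,-1.79,0.88,1.1,0.385423,,derived
thornton2021,52,daily_somatropin,height_sds,56,-3,0.9,-2.04,0.92,0.96,0.385423,,derived
thornton2021,52,lonapegsomatropin,igf1_sds,105,-2.08,0.88,0.3,0.95,2.38,0.770846,,derived
thornton2021,52,daily_somatropin,igf1_sds,56,-1.96,0.98,-0.44,1,1.52,0.770846,,derived
thornton2021,52,lonapegsomatropin,ba_ca_ratio,105,0.69,0.16,0.75,0.15,0.06,,,synthetic
thornton2021,52,daily_somatropin,ba_ca_ratio,56,0.7,0.14,0.75,0.13,0.05,,,synthetic
thornton2021,52,lonapegsomatropin,sae,105,,,,,,,3,synthetic
thornton2021,52,daily_somatropin,sae,56,,,,,,,1,synthetic
deal2022,52,somatrogon,ahv,109,,,10.1,2.3,,,,synthetic
deal2022,52,daily_somatropin,ahv,115,,,9.9,2.2,,,,synthetic
deal2022,52,somatrogon,height_sds,109,-2.94,1.29,-2.02,1.25,0.92,0.42,,synthetic
deal2022,52,daily_somatropin,height_sds,115,-2.78,1.27,-1.9,1.22,0.88,0.4,,synthetic
deal2022,52,somatrogon,igf1_sds,109,-1.95,,1.15,1.1,3.1,1.10685,,derived
deal2022,52,daily_somatropin,igf1_sds,115,-1.72,,-0.19,1,1.53,1.10685,,derived
deal2022,52,somatrogon,ba_ca_ratio,109,,,,,0.08,0.1,,synthetic
deal2022,52,daily_somatropin,ba_ca_ratio,115,,,,,0.06,0.09,,synthetic
deal2022,52,somatrogon,sae,109,,,,,,,6,synthetic
deal2022,52,daily_somatropin,sae,115,,,,,,,10,synthetic
miller2022,52,somapacitan,ahv,132,,,10,2.78167,,,,derived
miller2022,52,daily_somatropin,ahv,68,,,10.6,2.78167,,,,derived
miller2022,52,somapacitan,height_sds,132,-2.99,1.02,-2.2,1,0.79,0.639458,,derived
miller2022,52,daily_somatropin,height_sds,68,-3.47,1.52,-2.52,1.3,0.95,0.639458,,derived
miller2022,52,somapacitan,igf1_sds,132,-2.03,0.97,-0.43,1.05,1.6,1.15356,,derived
miller2022,52,daily_somatropin,igf1_sds,68,-2.33,1.03,-0.76,1.1,1.57,1.15356,,derived
miller2022,52,somapacitan,ba_ca_ratio,132,,,,,0.05,0.08,,synthetic
miller2022,52,daily_somatropin,ba_ca_ratio,68,,,,,0.06,0.09,,synthetic
miller2022,52,somapacitan,sae,132,,,,,,,4,synthetic
miller2022,52,daily_somatropin,sae,68,,,,,,,2,synthetic
horikawa2022,52,somatrogon,ahv,22,,,10.4,2,,,,synthetic
horikawa2022,52,daily_somatropin,ahv,22,,,9.2,1.9,,,,synthetic
horikawa2022,52,somatrogon,height_sds,22,-2.61,0.44,-1.76,0.5,0.85,0.35,,synthetic
horikawa2022,52,daily_somatropin,height_sds,22,-2.53,0.4,-1.93,0.45,0.6,0.33,,synthetic
horikawa2022,52,somatrogon,igf1_sds,22,-1.39,0.9,1.61,0.95,3,0.9,,synthetic
horikawa2022,52,daily_somatropin,igf1_sds,22,-1.62,0.84,-0.42,0.9,1.2,0.85,,synthetic
horikawa2022,52,somatrogon,ba_ca_ratio,22,,,,,0.04,0.06,,synthetic
horikawa2022,52,daily_somatropin,ba_ca_ratio,22,,,,,0.05,0.07,,synthetic
horikawa2022,52,somatrogon,sae,22,,,,,,,2,synthetic
horikawa2022,52,daily_somatropin,sae,22,,,,,,,2,synthetic
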