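trial_id,outcome,treatment_a,treatment_b,md,cri_lower,cri_upper,level,provenance
thornton2021,ahv,lonapegsomatropin,daily_somatropin,0.90,0.19,1.61,direct,printed
,ahv,lonapegsomatropin,somapacitan,1.50,0.42,2.58,indirect,printed
thornton2021,height_sds,lonapegsomatropin,daily_somatropin,0.14,0.02,0.27,direct,printed
,height_sds,lonapegsomatropin,somapacitan,0.30,0.08,0.53,indirect,printed
thornton2021,igf1_sds,lonapegsomatropin,daily_somatropin,0.86,0.61,1.11,direct,printed
deal2022,igf1_sds,somatrogon,daily_somatropin,1.57,1.28,1.86,direct,printed
,igf1_sds,somatrogon,lonapegsomatropin,0.71,0.33,1.09,indirect,printed
,igf1_sds,somatrogon,somapacitan,1.54,1.10,1.98,indirect,printed
,igf1_sds,lonapegsomatropin,somapacitan,0.83,0.41,1.25,indirect,printed
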