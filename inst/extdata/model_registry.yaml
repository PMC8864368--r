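# A priori regression models of site-level SES values.
# Terms refer to columns of the transformed predictor table
# (see transform_predictors()); "a:b" denotes an interaction.
- name: biogeography_1
  terms: [latitude]
- name: biogeography_2
  terms: [latitude, margin, ocean]
- name: biogeography_3
  terms: [latitude, margin, "latitude:margin"]
- name: biogeography_4
  terms: [latitude, margin, ocean, "latitude:margin"]
- name: biogeography_5
  terms: [latitude, margin, ocean, "latitude:margin", "latitude:ocean"]
- name: abiotic_environment
  terms: [temp_insitu, salinity, leaf_n]
- name: temperature_regime_1
  terms: [sst_mean]
- name: temperature_regime_2
  terms: [sst_range]
- name: temperature_regime_3
  terms: [sst_mean, sst_range, "sst_mean:sst_range"]
- name: community
  terms: [log_crustacean_abundance, median_crustacean_size]
- name: total_biodiversity
  terms: [log_epifaunal_richness]
- name: peracarid_biodiversity
  terms: [log_peracarid_richness]
- name: habitat
  terms: [pc1, pc2, log_macroalgae]
- name: predation
  terms: [arcsin_predation]
- name: resource_1
  terms: [log_epiphyte, log_chla]
- name: resource_2
  terms: [nitrogen_oxide_surface, par]
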