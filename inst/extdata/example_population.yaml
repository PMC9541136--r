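# Example target-population declaration matching example_scenario.yaml.
geo_extent:
  bbox: [0.0, 0.0, 12.0, 12.0]
temporal_extent: [1950, 2019]
taxa:
  - sp_common
  - sp_scarce
  - sp_rare
spatial_resolution: 1.0
temporal_resolution: 10
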