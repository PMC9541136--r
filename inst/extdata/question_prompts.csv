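# Signalling-question prompts for the risk-of-bias assessment document.
# These paraphrase the published checklist's intent; ids are stable, text is
# editable. section: research_statement|resolution|geographic|environmental|
# taxonomic|other. role: scope|provenance|representativeness|
# temporal_consistency|mitigation|other_bias.
id,section,role,prompt
1.1,research_statement,scope,"Define the statistical target population about which inferences are desired, including the extents of all relevant domains (geographic, temporal, taxonomic, environmental) and the resolutions at which analyses will be conducted."
1.2,research_statement,scope,"State the inferential goal of the study (e.g. to estimate temporal trends in species' occupancy over the declared population)."
1.3,research_statement,provenance,"Document the provenances of all datasets used: where each came from, how it was collected, and any access or licensing constraints relevant to interpretation."
1.4,research_statement,provenance,"Explain and justify every step taken to modify or clean the data, with counts of records affected by each step."
2.1,resolution,scope,"Specify the geographic, temporal and taxonomic resolutions (grain sizes) at which this bias assessment is conducted, and confirm they match the resolutions at which inferences are desired."
2.2,geographic,representativeness,"Are the data representative of the geographic domain; that is, do records cover the whole declared spatial extent evenly (ideally as a random sample would)?"
2.3,geographic,temporal_consistency,"Has the same portion of geographic space been sampled over time, or is there indication of temporal change in spatial coverage (space-time confounding)?"
2.4,geographic,mitigation,"If geographic biases were indicated above, how will they be mitigated, or why are they not relevant to the inferential goal?"
2.5,environmental,representativeness,"Are the data representative of the environmental domain; that is, do records cover the occupied regions of the declared environmental space?"
2.6,environmental,temporal_consistency,"Has the same portion of environmental space been sampled over time, or has environmental coverage shifted between periods?"
2.7,environmental,mitigation,"If environmental biases were indicated above, how will they be mitigated, or why are they not relevant to the inferential goal?"
2.8,taxonomic,representativeness,"Are the data representative of the taxonomic domain; that is, are records available across the full target taxon list rather than a preferred subset?"
2.9,taxonomic,temporal_consistency,"Have the same taxa been recorded over time, or is there indication of temporal turnover in taxonomic coverage?"
2.10,taxonomic,mitigation,"If taxonomic biases were indicated above, how will they be mitigated, or why are they not relevant to the inferential goal?"
2.11,other,other_bias,"Are there temporal biases unrelated to the ecological states of interest (e.g. changes in observation effort, detection probability, or revisit structure) that could bias estimated trends?"
2.12,other,other_bias,"Are there any other potential biases not covered above (e.g. phenological mismatch of sampling dates, temporal baselines, geographic variation in taxonomic coverage)?"
2.13,other,mitigation,"If other biases were indicated above, how will they be mitigated, or why are they not relevant to the inferential goal?"
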