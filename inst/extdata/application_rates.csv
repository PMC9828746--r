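chemical_id,pur_rate_kg_ha,pur_provenance,orchard_rate_kg_ha
trisiloxane_317,1.42,neat_max,2.056
trisiloxane_OH,0.404,p90_mixture,0.380
trisiloxane_acetoxy,0.688,p90_mixture,0.260
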