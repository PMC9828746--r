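chemical_id,endpoint,value,is_greater_than,method,ci_low,ci_high
trisiloxane_317,adult_contact_ld50,43.67,FALSE,tsk,37.30,51.13
trisiloxane_317,adult_oral_ld50,285.16,FALSE,tsk,247.84,328.10
trisiloxane_317,adult_chronic_noed,85.9,FALSE,williams,,
trisiloxane_317,larval_acute_ld50,100,TRUE,unbounded_highest_dose,,
trisiloxane_317,larval_chronic_noed,33,FALSE,fisher_holm,,
trisiloxane_OH,adult_contact_ld50,100,TRUE,unbounded_highest_dose,,
trisiloxane_OH,adult_oral_ld50,100,TRUE,unbounded_highest_dose,,
trisiloxane_OH,adult_chronic_noed,12.8,FALSE,williams,,
trisiloxane_OH,larval_acute_ld50,100,TRUE,unbounded_highest_dose,,
trisiloxane_OH,larval_chronic_noed,40,FALSE,cochran_armitage_stepdown,,
trisiloxane_acetoxy,adult_contact_ld50,150,TRUE,unbounded_highest_dose,,
trisiloxane_acetoxy,adult_oral_ld50,304,TRUE,unbounded_highest_dose,,
trisiloxane_acetoxy,adult_chronic_noed,94,FALSE,williams,,
trisiloxane_acetoxy,larval_acute_ld50,100,TRUE,unbounded_highest_dose,,
trisiloxane_acetoxy,larval_chronic_noed,33,FALSE,fisher_holm,,
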