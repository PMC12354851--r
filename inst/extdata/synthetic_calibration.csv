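"sample_id","known_activity_bq","ref_time_s","counts","window_start_s","window_end_s"
"dot1",0.01,0,4582,0,295200
"dot2",0.1,0,46385,0,295200
"dot3",1,0,464029,0,295200
"dot4",10,0,4648867,0,295200
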