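{"windows":[[0,21600]],"reference_time_label":"t0"}
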