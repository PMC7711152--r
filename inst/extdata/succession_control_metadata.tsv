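sample_id	substrate_bin	incubation	is_control
control_01	control	NA	TRUE
control_02	control	NA	TRUE
control_03	control	NA	TRUE
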