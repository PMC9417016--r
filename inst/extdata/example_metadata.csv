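respondent_id,group
r01,researcher
r02,ngo_member
r03,tour_operator
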