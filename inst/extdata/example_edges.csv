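respondent_id,source,target,sign
r01,fires,forest,-1
r01,fires,lemurs,-1
r01,zebu raising,fires,1
r01,local people,zebu raising,1
r01,forest,lemurs,1
r01,rivers,water provisioning,1
r01,tourism,,
r02,burning,forests,-1
r02,hunting,lemurs,-1
r02,local people,hunting,1
r02,forests,water provisioning,1
r02,tourism,local people,1
r03,fires,gallery forest,-1
r03,zebu raising,burning,1
r03,local people,water provisioning,1
r03,erosion,rivers,-1
r03,lemurs,tourism,1
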