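raw_label,component,type,category
forest,forest,habitats,biophysical
forests,forest,habitats,biophysical
gallery forest,forest,habitats,biophysical
lemurs,lemurs,flagship_species,biophysical
Lemur,lemurs,flagship_species,biophysical
rivers,rivers,geomorphology,biophysical
local people,local_people,local_stakeholders,social
zebu raising,zebu_raising,agriculture_husbandry,social
cattle raising,zebu_raising,agriculture_husbandry,social
tourism,tourism,new_activities,positive_human_action
fires,fires,environmental_threats,negative_human_action
burning,fires,environmental_threats,negative_human_action
hunting,hunting,environmental_threats,negative_human_action
water provisioning,water_provisioning,provisioning_services,ecosystem_service
erosion,erosion,land_degradation,ecosystem_disservice
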