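item,label,unit_cost,source
gp_visit,GP visit,42,Personal Social Services Research Unit
gp_phone,GP telephone call,41.13,Personal Social Services Research Unit
nurse_visit,Nurse visit,11.31,Literature
nurse_phone,Nurse telephone call,11.31,Literature
lc_nurse,Specialist LC nurse,28.5,Personal Social Services Research Unit
physiotherapist,Physiotherapist,73.14,NHS Reference costs
occupational_therapist,Occupational therapist,99.11,NHS Reference costs
community_nurse,Community nurse,23,Personal Social Services Research Unit
health_visitor,Health visitor,94.25,NHS reference costs
social_worker,Social worker,50,Personal Social Services Research Unit
home_care,Home care,23,Personal Social Services Research Unit
hospitalisation,Hospitalisation (overnight),586.59,Literature
ae_visit,A&E visit,148,Scottish Health Services Costs
day_hospital,Day hospital visit,251,Scottish Health Services Costs
outpatient,Outpatient department appointment,165,NHS Reference costs
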