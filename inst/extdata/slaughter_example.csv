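flock_id,sample_size,weight_range,farm_weight,total_hematoms,broken_wing,hematoma_wings,hematoma_armpit,breast,broken_bones,overscalded,bad_extraction_viscera,bad_plucked,bad_wash,scab,crops,knuckles,dead_in_transport,confiscated,numbers_of_chickens,meat_quality
lot-2019-04-30,200,3.42,3.42,23,21,11,0,12,9,0,1,0,0,0,0,0,3,8,5040,A
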