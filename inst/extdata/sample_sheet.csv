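sample_id,strain,induced,total_protein_sn,true_sn_AprBp,true_sn_GseBp,true_vial_AprBp,true_vial_GseBp
Bp3_19,B_pumilus_3-19,FALSE,4.5,1.63,1.3,5.97666666666667,4.76666666666667
AT1,AT1,FALSE,0.32,0,0,0,0
MRB044_unind,MRB044,FALSE,2,0.024,0,0.198,0
MRB044_ind,MRB044,TRUE,5,1.5,0,4.95,0
MRB046_unind,MRB046,FALSE,1.3,0.005,0,0.0634615384615385,0
MRB046_ind,MRB046,TRUE,1.8,0.03,0,0.275,0
MRB047_unind,MRB047,FALSE,1.2,0,0.00036,0,0.00495
MRB047_ind,MRB047,TRUE,1.65,0,0.005,0,0.05
MRB049_unind,MRB049,FALSE,2.06,0,0.006,0,0.0480582524271845
MRB049_ind,MRB049,TRUE,3.2,0,0.06,0,0.309375
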