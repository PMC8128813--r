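patient_id,age,figo_stage,days_biopsy_to_ct,site,n_biopsies,n_habitats,volume_cm3,biopsy_result,weight_kg,dsc
1,59,3C,30,omentum,1,3,15.7,insufficient material,61,NA
2,59,4B,10,pelvis,3,3,591.7,HGSOC,69,0.76
3,53,4A,29,omentum,2,3,295.2,insufficient material,77,0.37
4,68,3C,16,omentum,4,3,19.4,HGSOC,72,0.43
5,76,4A,7,pelvis,4,3,448.3,HGSOC,66,0.79
6,77,4B,26,omentum,3,3,187.4,HGSOC,94,0.53
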