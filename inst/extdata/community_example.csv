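site_id,sample_id,taxon,abundance,sampling_area,sampling_depth,layers,method,latitude,longitude,habitat,soil_temperature
DE01,DE01_1,Folsomia,34,0.0025,5,litter+soil,tullgren,51.5,10.2,woodland,8.1
DE01,DE01_1,Isotomiella,12,0.0025,5,litter+soil,tullgren,51.5,10.2,woodland,8.1
DE01,DE01_1,Lepidocyrtus,5,0.0025,5,litter+soil,tullgren,51.5,10.2,woodland,8.1
DE01,DE01_2,Folsomia,21,0.0025,5,litter+soil,tullgren,51.5,10.2,woodland,8.1
DE01,DE01_2,Sminthurinus,3,0.0025,5,litter+soil,tullgren,51.5,10.2,woodland,8.1
DE01,DE01_3,Parisotoma,9,0.0025,5,litter+soil,tullgren,51.5,10.2,woodland,8.1
NO01,NO01_1,Folsomia,112,0.001,3,litter+soil,tullgren,69.2,18.5,scrub,0.5
NO01,NO01_1,Hypogastrura,48,0.001,3,litter+soil,tullgren,69.2,18.5,scrub,0.5
NO01,NO01_2,Folsomia,85,0.001,3,litter+soil,tullgren,69.2,18.5,scrub,0.5
NO01,NO01_2,Megalothorax,14,0.001,3,litter+soil,tullgren,69.2,18.5,scrub,0.5
BR01,BR01_1,Isotomiella,6,0.005,5,litter+soil,berlese,-3.1,-60.0,woodland,26.4
BR01,BR01_1,Cyphoderus,2,0.005,5,litter+soil,berlese,-3.1,-60.0,woodland,26.4
BR01,BR01_2,Seira,4,0.005,5,litter+soil,berlese,-3.1,-60.0,woodland,26.4
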