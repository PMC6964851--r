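item,All-74,CT-74,All-16,CT-16,LI,AR,PF
equipment,28862,26582,28862,26582,2280,1160,1120
vehicle,2000,400,2000,800,2000,2000,2000
consumables,620,500,236,116,120,0,120
labour_h,225,41,235,51,184,173,176
deploy_labour_h,55,,55,,55,15,40
deploy_vehicle,300,,300,,300,300,300
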