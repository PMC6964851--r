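species,common_name,size_class,All-74,CT-74,All-16,CT-16,LI,AR,PF
Lampropholis delicata,Delicate skink,small_lizard,10,10,10,10,10,10,7
Saproscincus mustelinus,Weasel skink,small_lizard,2,2,2,2,2,1,1
Acritoscincus platynota,Red-throated skink,medium_large_lizard,2,2,1,0,1,1,1
Amphibolurus muricatus,Jacky dragon,medium_large_lizard,10,10,8,8,4,1,4
Ctenotus taeniolatus,Copper-tailed skink,medium_large_lizard,8,8,4,4,2,0,2
Cyclodomorphus michaeli,Mainland she-oak skink,medium_large_lizard,5,2,4,1,4,3,1
Tiliqua scincoides,Blue-tongue skink,medium_large_lizard,6,6,2,2,0,0,0
Hemiaspis signata,Marsh snake,snake,6,3,6,2,5,5,0
Pseudechis porphyriacus,Red-bellied black snake,snake,7,7,3,3,0,0,0
Pseudonaja textilis,Eastern brown snake,snake,4,3,3,2,2,2,0
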