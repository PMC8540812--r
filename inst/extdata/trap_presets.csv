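key,insect,trap_type,sptfer0,d50,d50_sem,rmax,rmax_estimated
l_dispar,Lymantria dispar,pheromone,0.37,27.3,3,1600,FALSE
codling_moth,Cydia pomonella,pheromone,0.7,6.5,1,260,TRUE
stink_bug,Halyomorpha halys,pheromone,0.5,7,0.9,130,TRUE
pine_sawfly,Neodiprion sertifer,pheromone,0.09,250,21,1040,FALSE
drosophila,Drosophila suzukii,chemical,0.02,27.7,7,90,TRUE
corn_rootworm,Diabrotica virgifera,pheromone,0.09,11,0.4,60,TRUE
southern_pine_beetle,Dendroctonus frontalis,pheromone,0.08,23,2.8,1000,FALSE
douglas_fir_beetle,Dendroctonus pseudotsugae,pheromone,0.07,184,33,600,FALSE
erebidae,Erebidae assemblage,light,0.52,10.6,1.4,40,FALSE
sphingidae,Sphingidae assemblage,light,0.31,91.6,8,175,TRUE
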