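species,taxon_group,n_offspring,offspring_mass,breeder_mass,brood_masses,source
Atlantic cod,fish,1000000,0.0006,8000,,synthetic example values
Loggerhead sea turtle,reptile,100-120,20,135000,,synthetic example values
African elephant,mammal,1,850000,3000000,,synthetic example values
Red-winged blackbird,bird,2-4,34,41,38;36;31,synthetic example values
Great white shark,shark,5,25000,1100000,26000;25000;24000;23000;22000,synthetic example values
Shedao pit viper,reptile,2-8,10,200,,synthetic example values
Fire ant,social insect,100000,0.012,0.02,,synthetic example values
Naked mole-rat,social mammal,12,15,50,,synthetic example values
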