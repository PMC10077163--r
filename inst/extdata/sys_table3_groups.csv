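group,size,taxa,body_length_class,feeding_type,trophic_group,reproductive_mode
1,30,Copepods; Cumaceans; Tunicates,small; medium; large; giant,active_ambush; current; mixed,omnivore_herbivore,free_spawner; egg_brooding
2,7,Amphipods; Chaetognaths; Polychaetes,giant,active_ambush,carnivore,free_spawner; egg_brooding
3,29,Ctenophores; Hydromedusae; Siphonophorae,small; medium; large; giant,passive_ambush,carnivore,free_spawner
4,12,Copepods,small; medium; large,active_ambush,omnivore_carnivore,free_spawner; egg_brooding
5,9,Copepods; Ostracods,small; medium,current,omnivore_detritivore,free_spawner; egg_brooding
6,2,Cladocerans,medium,active_ambush; current,omnivore_carnivore; omnivore_herbivore,parthenogenesis
7,3,Tunicates,medium; large,current,omnivore_herbivore,alternation_of_generations
8,6,Decapods; Euphausiids; Mysids,giant,mixed,omnivore; omnivore_carnivore,free_spawner; egg_brooding
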