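taxon_group,season,n_species,mean_abundance,sd_abundance,below_detection
Hydromedusae,spring,4,1.6,3.5,FALSE
Hydromedusae,summer,22,22.3,35.6,FALSE
Hydromedusae,autumn,13,0.7,1.2,FALSE
Siphonophorae,spring,NA,NA,NA,FALSE
Siphonophorae,summer,2,32.4,50.8,FALSE
Siphonophorae,autumn,3,1.0,2.5,FALSE
Ctenophores,spring,NA,NA,NA,FALSE
Ctenophores,summer,2,0.7,1.7,FALSE
Ctenophores,autumn,1,0.3,0.6,FALSE
Polychaetes,spring,NA,NA,NA,FALSE
Polychaetes,summer,1,0.05,NA,TRUE
Polychaetes,autumn,NA,NA,NA,FALSE
Ostracods,spring,NA,NA,NA,FALSE
Ostracods,summer,1,0.05,NA,TRUE
Ostracods,autumn,NA,NA,NA,FALSE
Cladocerans,spring,1,0.3,0.9,FALSE
Cladocerans,summer,2,78.1,271.3,FALSE
Cladocerans,autumn,1,0.5,1.2,FALSE
Copepods,spring,18,1262.7,1327.5,FALSE
Copepods,summer,40,1609.1,1769.2,FALSE
Copepods,autumn,25,1258.0,990.3,FALSE
Amphipods,spring,2,2.2,3.9,FALSE
Amphipods,summer,3,10.0,18.6,FALSE
Amphipods,autumn,2,6.7,9.9,FALSE
Isopods,spring,NA,NA,NA,FALSE
Isopods,summer,1,0.05,NA,TRUE
Isopods,autumn,1,0.05,NA,TRUE
Cumaceans,spring,NA,NA,NA,FALSE
Cumaceans,summer,1,0.05,NA,TRUE
Cumaceans,autumn,2,0.1,0.3,FALSE
Mysids,spring,NA,NA,NA,FALSE
Mysids,summer,NA,NA,NA,FALSE
Mysids,autumn,1,0.4,0.9,FALSE
Euphausiids,spring,2,0.5,0.8,FALSE
Euphausiids,summer,2,1.8,2.0,FALSE
Euphausiids,autumn,2,1.1,2.1,FALSE
Decapods,spring,1,0.05,NA,TRUE
Decapods,summer,3,4.7,8.5,FALSE
Decapods,autumn,1,0.1,0.2,FALSE
Chaetognaths,spring,2,6.4,8.0,FALSE
Chaetognaths,summer,3,90.0,70.3,FALSE
Chaetognaths,autumn,3,46.0,55.3,FALSE
Tunicates,spring,2,8.7,26.7,FALSE
Tunicates,summer,4,46.9,44.3,FALSE
Tunicates,autumn,3,45.4,64.9,FALSE
Pelagic larvae,spring,13,285.9,675.3,FALSE
Pelagic larvae,summer,22,205.1,545.6,FALSE
Pelagic larvae,autumn,15,50.3,112.9,FALSE
Total,spring,45,1568.2,1797.1,FALSE
Total,summer,109,2102.4,1995.0,FALSE
Total,autumn,73,1328.6,1031.5,FALSE
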