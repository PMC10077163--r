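species,season,mean_abundance,sd_abundance,dominance,below_detection
Calanus sinicus,spring,202.4,269.3,0.11,FALSE
Calanus sinicus,summer,52.8,46.5,0.03,FALSE
Calanus sinicus,autumn,33.7,36.3,0.03,FALSE
Paracalanus parvus,spring,242.1,310.4,0.08,FALSE
Paracalanus parvus,summer,546.9,316.4,0.29,FALSE
Paracalanus parvus,autumn,874.9,747.4,0.64,FALSE
Centropages dorsispinatus,spring,NA,NA,NA,FALSE
Centropages dorsispinatus,summer,320.1,1225.6,0.05,FALSE
Centropages dorsispinatus,autumn,0.05,NA,0.005,TRUE
Centropages abdominalis,spring,208.1,584.1,0.09,FALSE
Centropages abdominalis,summer,NA,NA,NA,FALSE
Centropages abdominalis,autumn,NA,NA,NA,FALSE
Acartia pacifica,spring,0.05,NA,0.005,TRUE
Acartia pacifica,summer,128.5,366.5,0.04,FALSE
Acartia pacifica,autumn,2.4,6.7,0.005,TRUE
Oithona similis,spring,546.4,989.5,0.52,FALSE
Oithona similis,summer,198.8,292.8,0.12,FALSE
Oithona similis,autumn,202.8,262.3,0.17,FALSE
Oithona plumifera,spring,11.2,24.2,0.005,TRUE
Oithona plumifera,summer,81.4,102.4,0.04,FALSE
Oithona plumifera,autumn,3.8,6.9,0.005,TRUE
Corycaeus affinis,spring,19.6,28.9,0.01,FALSE
Corycaeus affinis,summer,50.1,41.9,0.02,FALSE
Corycaeus affinis,autumn,86.6,173.2,0.02,FALSE
Oikopleura dioica,spring,8.5,26.3,0.005,TRUE
Oikopleura dioica,summer,40.8,42.8,0.02,FALSE
Oikopleura dioica,autumn,45.0,64.7,0.03,FALSE
Bivalve larvae,spring,208.0,650.1,0.07,FALSE
Bivalve larvae,summer,9.5,18.5,0.005,TRUE
Bivalve larvae,autumn,16.2,51.2,0.005,TRUE
Polychaeta larvae,spring,1.1,2.8,0.005,TRUE
Polychaeta larvae,summer,153.2,519.3,0.07,FALSE
Polychaeta larvae,autumn,6.3,12.3,0.005,TRUE
Copepod nauplii,spring,55.3,57.3,0.04,FALSE
Copepod nauplii,summer,13.6,25.5,0.005,TRUE
Copepod nauplii,autumn,4.9,8.1,0.005,TRUE
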