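diet_id,nutrient,adc
D1,arginine,93.5
D1,histidine,87.8
D1,isoleucine,87
D1,leucine,88.4
D1,lysine,89.4
D1,methionine,88.5
D1,phenylalanine,88.8
D1,threonine,85.6
D1,valine,87.3
D1,alanine,89.4
D1,aspartic_acid,84.3
D1,cysteine,60.9
D1,glutamic_acid,88.7
D1,glycine,91.5
D1,proline,90.6
D1,serine,90.6
D1,tyrosine,86.9
D1,taurine,43.5
D2,arginine,97.9
D2,histidine,95.7
D2,isoleucine,94.9
D2,leucine,95.2
D2,lysine,96.3
D2,methionine,95.9
D2,phenylalanine,95.2
D2,threonine,93.5
D2,valine,94.5
D2,alanine,95.3
D2,aspartic_acid,92.3
D2,cysteine,77.3
D2,glutamic_acid,95.5
D2,glycine,95.3
D2,proline,96
D2,serine,96
D2,tyrosine,94.6
D2,taurine,71.2
D3,arginine,95.1
D3,histidine,90.3
D3,isoleucine,89.9
D3,leucine,90.6
D3,lysine,92.7
D3,methionine,93.9
D3,phenylalanine,90.8
D3,threonine,86.1
D3,valine,89.4
D3,alanine,90.3
D3,aspartic_acid,84.8
D3,cysteine,56.5
D3,glutamic_acid,91.1
D3,glycine,89.4
D3,proline,91.8
D3,serine,91.8
D3,tyrosine,89.1
D3,taurine,34.3
D4,arginine,92.9
D4,histidine,87.3
D4,isoleucine,88.6
D4,leucine,88.9
D4,lysine,90.8
D4,methionine,93.1
D4,phenylalanine,89.3
D4,threonine,85.7
D4,valine,87.4
D4,alanine,89.2
D4,aspartic_acid,82.7
D4,cysteine,54.2
D4,glutamic_acid,89.6
D4,glycine,88.8
D4,proline,90.2
D4,serine,90.2
D4,tyrosine,88.2
D4,taurine,39.2
D5,arginine,93.4
D5,histidine,87.5
D5,isoleucine,87.9
D5,leucine,88.7
D5,lysine,91
D5,methionine,94.2
D5,phenylalanine,89.4
D5,threonine,84.7
D5,valine,86.9
D5,alanine,89.6
D5,aspartic_acid,84
D5,cysteine,53.9
D5,glutamic_acid,90
D5,glycine,88.2
D5,proline,90
D5,serine,90
D5,tyrosine,87.7
D5,taurine,23
D6,arginine,94.3
D6,histidine,90.6
D6,isoleucine,90.6
D6,leucine,91.4
D6,lysine,92.2
D6,methionine,94.7
D6,phenylalanine,91.9
D6,threonine,88.4
D6,valine,90.2
D6,alanine,91.6
D6,aspartic_acid,86.4
D6,cysteine,65.3
D6,glutamic_acid,92
D6,glycine,91
D6,proline,92.7
D6,serine,92.7
D6,tyrosine,90.3
D6,taurine,86.4
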