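diet_id,arginine,histidine,isoleucine,leucine,lysine,methionine,phenylalanine,threonine,valine,alanine,aspartic_acid,cysteine,glutamic_acid,glycine,proline,serine,tyrosine,taurine,marker,dry_matter,gross_energy
D1,31.2,12,15.8,34.2,29.1,9.5,23.9,20,21.4,32.4,48,4.4,78.3,62.7,34.5,24.2,14.9,1.8,1,0.906,19.5
D2,35.3,13.1,16.2,34,33.2,11.6,22.3,19.7,20.7,31.4,47.6,4.3,78.5,55.4,34,24.5,14.2,1.7,1,0.884,19.1
D3,33.1,13.1,17.1,34.6,32.8,14,23.2,20.2,22.2,32.8,47.8,4.3,80.4,50.5,34.8,24.8,14.7,1.7,1,0.864,18.8
D4,33.9,12.5,17.3,36,33,17.9,24.3,21.5,22.8,33.9,49.7,4.7,83.5,55.6,35.7,25.8,15.5,1.9,1,0.913,19.7
D5,30.7,11.8,15.9,33,29.2,21.5,22.3,19.2,20.7,31.9,46.8,4.2,78,49.2,33,23.8,14.5,1.7,1,0.873,19.1
D6,34.3,14,17.8,36.8,31.6,18.6,25.6,21.2,22.7,34.4,51.2,4.9,87.2,54.1,37.7,27,15.7,8,1,0.917,18.3
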