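river,nitrate_ug_per_l,chlorophyll_ug_per_l
Navia,0.1,0.1
Eume,6.4,0.1
Tambre,23.2,0.1
"Ulla, Ulmia",13.3,0.1
Verdugo,4.4,0.1
Minho,34.7,2.0
Lima,11.8,2.4
Cavado,33.2,0.9
Douro,88.5,5.4
Vouga,44.4,0.1
Mondego,2.3,5.0
Tejo,21.0,8.5
Sado,21.3,9.6
Mira,10.6,0.9
Guadiana,5.2,0.1
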