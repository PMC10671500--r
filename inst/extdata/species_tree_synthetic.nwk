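(D_melanogaster:290,(P_xylostella:140,((C_pomonella:95,A_transitella:95):25,((P_xuthus:95,(P_rapae:85,(D_plexippus:75,(M_cinxia:65,H_melpomene:65):10):10):10):13,((B_mori:75,M_sexta:75):20,(T_ni:80,(H_armigera:45,S_litura:45):35):15):13):12):20):150);
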