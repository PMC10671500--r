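# Serpin family sizes on the synthetic dated species tree. Counts for
# C_pomonella (26), B_mori (34), H_armigera (26) and D_melanogaster (29) are
# the published family sizes; the remaining species carry synthetic
# stand-in counts consistent with an ancestral Lepidoptera family of ~28.
# Dating calibration windows used in the original study (metadata only):
# B_mori--P_xylostella 50-80 Mya; S_litura--T_ni 70-90 Mya.
species	count
D_melanogaster	29
P_xylostella	25
C_pomonella	26
A_transitella	23
B_mori	34
M_sexta	31
T_ni	28
H_armigera	26
S_litura	30
P_xuthus	40
P_rapae	21
D_plexippus	28
M_cinxia	28
H_melpomene	28
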