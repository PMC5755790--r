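key	smarts
alkane_carbon	[CX4]
methyl	[CX4H3]
chain_c4	[CX4][CX4][CX4][CX4]
alkene	[CX3]=[CX3]
alkyne	[CX2]#[CX2]
aromatic_atom	a
benzene_ring	c1ccccc1
aromatic_n	[n]
aromatic_o	[o]
aromatic_s	[s]
hetero_aromatic	[a;!c]
ring_atom	[R]
ring3	[r3]
ring4	[r4]
ring5	[r5]
ring6	[r6]
hydroxyl	[OX2H]
primary_alcohol	[OX2H][CX4H2]
secondary_alcohol	[OX2H][CX4H1]
tertiary_alcohol	[OX2H][CX4H0]
phenol	[OX2H][c]
ether	[OD2]([#6])[#6]
carbonyl	[CX3]=[OX1]
aldehyde	[CX3H1](=O)[#6]
ketone	[#6][CX3](=O)[#6]
carboxylic_acid	[CX3](=O)[OX2H1]
carboxylate	[CX3](=O)[O-]
ester	[#6][CX3](=O)[OX2H0][#6]
amide	[NX3][CX3](=[OX1])
urea	[NX3][CX3](=[OX1])[NX3]
carbamate	[NX3][CX3](=[OX1])[OX2]
primary_amine	[NX3H2]
secondary_amine	[NX3H1]([#6])[#6]
tertiary_amine	[NX3]([#6])([#6])[#6]
quaternary_n	[NX4+]
imine	[CX3]=[NX2]
nitrile	[NX1]#[CX2]
nitro	[$([NX3](=O)=O),$([NX3+](=O)[O-])]
thiol	[SX2H]
thioether	[SX2]([#6])[#6]
disulfide	[SX2][SX2]
sulfoxide	[$([SX3]=[OX1])]
sulfone	[$([SX4](=[OX1])(=[OX1]))]
phosphoryl	[PX4](=[OX1])
fluorine	[F]
chlorine	[Cl]
bromine	[Br]
iodine	[I]
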