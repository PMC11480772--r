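role,residue_class,atom_name,attached_hydrogen,comment
donor,protein,N,H,backbone amide
donor,protein,NE,HE,arginine guanidinium
donor,protein,NH1,HH11,arginine guanidinium
donor,protein,NH2,HH21,arginine guanidinium
donor,protein,NZ,HZ1,lysine ammonium
donor,protein,ND1,HD1,histidine imidazole
donor,protein,NE2,HE2,histidine imidazole
donor,protein,OG,HG,serine hydroxyl
donor,protein,OG1,HG1,threonine hydroxyl
donor,protein,OH,HH,tyrosine hydroxyl
donor,protein,ND2,HD21,asparagine amide
donor,protein,NE2,HE21,glutamine amide
donor,rna,O2',HO2',ribose 2'-hydroxyl
donor,rna,N1,H1,guanine imino
donor,rna,N3,H3,uracil imino
donor,rna,N2,H21,guanine amino
donor,rna,N4,H41,cytosine amino
donor,rna,N6,H61,adenine amino
acceptor,protein,O,,backbone carbonyl
acceptor,protein,OD1,,aspartate/asparagine
acceptor,protein,OD2,,aspartate
acceptor,protein,OE1,,glutamate/glutamine
acceptor,protein,OE2,,glutamate
acceptor,protein,OG,,serine hydroxyl
acceptor,protein,OG1,,threonine hydroxyl
acceptor,protein,OH,,tyrosine hydroxyl
acceptor,protein,ND1,,histidine imidazole
acceptor,rna,OP1,,phosphate
acceptor,rna,OP2,,phosphate
acceptor,rna,O2',,ribose hydroxyl
acceptor,rna,O3',,ribose
acceptor,rna,O4',,ribose ring
acceptor,rna,O5',,ribose
acceptor,rna,N1,,adenine ring
acceptor,rna,N3,,cytosine ring
acceptor,rna,N7,,purine ring
acceptor,rna,O2,,pyrimidine carbonyl
acceptor,rna,O4,,uracil carbonyl
acceptor,rna,O6,,guanine carbonyl
donor,toy,CA,HB,basic bead proxy
acceptor,toy,P1,,scaffold bead proxy
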