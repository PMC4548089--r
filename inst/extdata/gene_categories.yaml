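# Functional categories of plastid protein-coding genes used by gene_table().
# Four groups: photosynthetic apparatus (photosystem, cytochrome b6f and
# assembly factors), photosynthetic metabolism (ATP synthase, NADH
# dehydrogenase, Rubisco), gene expression (ribosomal proteins, RNA
# polymerase, translation), and other (conserved ORFs, maturase, proteases,
# envelope and heme proteins).
psaA: photosynthetic apparatus
psaB: photosynthetic apparatus
psaC: photosynthetic apparatus
psaI: photosynthetic apparatus
psaJ: photosynthetic apparatus
psbA: photosynthetic apparatus
psbB: photosynthetic apparatus
psbC: photosynthetic apparatus
psbD: photosynthetic apparatus
psbE: photosynthetic apparatus
psbF: photosynthetic apparatus
psbH: photosynthetic apparatus
psbI: photosynthetic apparatus
psbJ: photosynthetic apparatus
psbK: photosynthetic apparatus
psbL: photosynthetic apparatus
psbM: photosynthetic apparatus
psbN: photosynthetic apparatus
psbT: photosynthetic apparatus
psbZ: photosynthetic apparatus
petA: photosynthetic apparatus
petB: photosynthetic apparatus
petD: photosynthetic apparatus
petG: photosynthetic apparatus
petL: photosynthetic apparatus
petN: photosynthetic apparatus
ycf3: photosynthetic apparatus
ycf4: photosynthetic apparatus
atpA: photosynthetic metabolism
atpB: photosynthetic metabolism
atpE: photosynthetic metabolism
atpF: photosynthetic metabolism
atpH: photosynthetic metabolism
atpI: photosynthetic metabolism
ndhA: photosynthetic metabolism
ndhB: photosynthetic metabolism
ndhC: photosynthetic metabolism
ndhD: photosynthetic metabolism
ndhE: photosynthetic metabolism
ndhF: photosynthetic metabolism
ndhG: photosynthetic metabolism
ndhH: photosynthetic metabolism
ndhI: photosynthetic metabolism
ndhJ: photosynthetic metabolism
ndhK: photosynthetic metabolism
rbcL: photosynthetic metabolism
rpl2: gene expression
rpl14: gene expression
rpl16: gene expression
rpl20: gene expression
rpl22: gene expression
rpl23: gene expression
rpl32: gene expression
rpl33: gene expression
rpl36: gene expression
rps2: gene expression
rps3: gene expression
rps4: gene expression
rps7: gene expression
rps8: gene expression
rps11: gene expression
rps12: gene expression
rps14: gene expression
rps15: gene expression
rps16: gene expression
rps18: gene expression
rps19: gene expression
rpoA: gene expression
rpoB: gene expression
rpoC1: gene expression
rpoC2: gene expression
infA: gene expression
ycf1: other
ycf2: other
ycf15: other
ccsA: other
cemA: other
matK: other
clpP: other
accD: other
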