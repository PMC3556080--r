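gene	description	cytoband	mean_log2fc
POSTN	periostin, osteoblast specific factor	13q13.3	-2.21
MRPL30	mitochondrial ribosomal protein L30	2q11.2	-1.98
ENPP5	ectonucleotide pyrophosphatase/phosphodiesterase 5	6p12.3	-1.95
TGFb3	transforming growth factor, beta 3	14q24.3	-1.65
DDAH1	dimethylarginine dimethylaminohydrolase 1	1p22.3	-1.62
SI	sucrase-isomaltase	3q26.1	-1.53
NEDD9	Human enhancer of filamentation	6p25-p24	-0.91
TMCO1	transmembrane and coiled-coil domains 1	1q24.2	1.33
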