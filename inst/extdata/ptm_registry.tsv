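name	formula	mass	targets	class
phospho	HO3P	79.9663309	S,T,Y	phospho
acetyl	C2H2O	42.0105647	K,protein-nterm	acetyl
methyl	CH2	14.0156501	K,R,N	methyl
dimethyl	C2H4	28.0313001	K	dimethyl
formyl	CO	27.9949146	K	formyl
crotonyl	C4H4O	68.0262147	K	crotonyl
propionyl	C3H4O	56.0262147	K	propionyl
methylpyrroline	C6H7NO	109.0527638	K,T	methylpyrroline
phosphoglycerol	C3H7O5P	154.0031103	S,T	phosphoglycerol
K-adduct	C6H12N2O	128.0949630	K	aa-adduct
KV-adduct	C11H21N3O2	227.1633769	K	aa-adduct
KH-adduct	C12H19N5O2	265.1538749	K	aa-adduct
R-adduct	C6H12N4O	156.1011110	E	aa-adduct
unknown-84.020		84.0200000	K	unknown
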