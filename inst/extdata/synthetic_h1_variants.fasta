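>SYN-H1.2 met_removed=true domain=NTD:2-60 domain=GH1:61-131 domain=CTD:132-273 synthetic H1-like stand-in (28.45 kDa class)
SGSDGDSPSSDVDAKTDSKSPAKSAKEDAPVGGGGSEGEVGDPVSVSTESTVPVASKESKGIRALYIAYTKAYKSYVSVG
TKGTTISYTNNGFLLLSKAKSSTEKYIRRYLVAKPATFGTSYETGAASKGKKPVTVVKVKPKTKTPVKTKKVKGSKGGKV
VKKGSPVPSSPGKKKKPSSKPKGKKPKSGSKSKKKGGGKGGGVKVSPSGKPVKPSSPKSKTKTKKKKKTTTKTKVKKKKK
TKKKPVKTKVKTPKKKTKVTKTVTKKKKKTTV
>SYN-H1.1 met_removed=true domain=NTD:2-64 domain=GH1:65-135 domain=CTD:136-277 synthetic H1-like stand-in (28.92 kDa class)
SEGSEAEVVPSKSDATAPSSPAKPATTDTPEGASTEKAADADESAADAEDTTADVKGEATEAAYSKKTLRGKAIEGALKA
VIIAGTALINVAIIFEAVRGGSVKASSFVFRKLERKEGARYGGAIGKTLGLLEGSPKPPKKKPVKVPVTPVKKPKPKKST
STKVKKVKKSPSSKKKKVPKVTSGPSKKSSVTTTKKKKTKPPKKKTKGKKSKKPKKVTPKVKKKPKKPKKKPKSVPPPTS
TPKPKPKSTSSKSTVSPKKTVKPPSVSKTTKKKTAK
>SYN-H1.2s met_removed=true domain=NTD:2-60 domain=GH1:61-131 domain=CTD:132-203 synthetic splice-variant stand-in (21.56 kDa class)
SGSDGDSPSSDVDAKTDSKSPAKSAKEDAPVGGGGSEGEVGDPVSVSTESTVPVASKESKGIRALYIAYTKAYKSYVSVG
TKGTTISYTNNGFLLLSKAKSSTEKYIRRYLVAKPATFGTSYETGAASKGKKPVTVVKVKPKTKTPVKTKTKTKKKKKTT
TKTKVKKKKKTKKKPVKTKVKTPKKKTKVTKTVTKKKKKTTV
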