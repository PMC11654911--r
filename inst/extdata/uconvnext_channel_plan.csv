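layer_id,base,optimized,printed_reduction_pct
DSCL 01,32,37,-15.63
DSCL 02,128,141,-10.16
DSCL 03,32,44,-37.50
DSCL 04,64,41,35.94
DSCL 05,256,267,-4.30
DSCL 06,64,46,28.13
DSCL 07,256,301,-17.58
DSCL 08,64,96,-50.00
DSCL 09,128,118,7.81
DSCL 10,512,640,-25.00
DSCL 11,128,158,-23.44
DSCL 12,512,697,-36.13
DSCL 13,128,134,-4.69
DSCL 14,256,383,-49.61
DSCL 15,1024,853,16.70
DSCL 16,256,337,-31.64
DSCL 17,1024,656,35.94
DSCL 18,256,361,-41.02
DSCL 19,1024,674,34.18
DSCL 20,256,372,-45.31
DSCL 21,1024,681,33.50
DSCL 22,256,156,39.06
DSCL 23,1024,1469,-43.46
DSCL 24,256,166,35.16
DSCL 25,1024,1382,-34.96
DSCL 26,256,231,9.77
DSCL 27,256,176,31.25
DSCL 28,1024,703,31.35
DSCL 29,256,214,16.41
DSCL 30,1024,540,47.27
DSCL 31,256,303,-18.36
USCL 01,128,172,-34.38
USCL 02,512,418,18.36
USCL 03,128,169,-32.03
USCL 04,64,45,29.69
USCL 05,256,351,-37.11
USCL 06,64,94,-46.88
USCL 07,32,36,-12.50
USCL 08,128,101,21.09
USCL 09,32,28,12.50
USCL 10,32,24,25.00
USCL 11,128,135,-5.47
USCL 12,32,24,25.00
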