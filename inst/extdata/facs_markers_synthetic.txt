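# synthetic FACS-style surface-marker list for the fabricated reference (gene ids g0001..; not derived from any measured panel)
g0001
g0002
g0003
g0004
g0005
g0006
g0007
g0008
g0009
g0010
g0011
g0012
g0013
g0014
g0015
g0016
g0017
g0018
g0019
g0020
g0021
g0022
g0023
g0024
g0025
g0026
g0027
g0028
g0029
g0030
g0031
g0032
g0033
g0034
g0035
g0036
g0037
g0038
g0039
g0040
g0301
g0302
g0303
g0304
g0305
g0306
g0307
g0308
g0309
g0310
g0311
g0312
g0313
g0314
g0315
g0316
g0317
g0318
g0319
g0320
g0321
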