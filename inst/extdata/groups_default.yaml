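# Packaged default a priori gene groups: 12 skeletal muscle-specific,
# 9 common muscle, 6 heart muscle-specific, 26 non-muscle genes
# (fibroblast, endothelial, neuronal markers; Cd31 is an alias of
# Pecam1 and is listed once, as Pecam1).
skeletal:
- Neb
- Scn4a
- Cacna1s
- Tnni1
- Tnni2
- Myh1
- Myh2
- Myh3
- Myh4
- Myogenin
- Myod1
- Ryr1
common:
- Actn2
- Kcnj2
- Mef2C
- Myh6
- Myl2
- Sln
- Ttn
- Myoglobin
- Myh7
heart:
- Cacna1c
- Kcna4
- Nebl
- Ryr2
- Scn5a
- Tnni3
nonmuscle:
- Col1a2
- S100a4
- Thy1
- Tcf21
- Atl1
- Col1a1
- Postn
- Cdh1
- Eng
- Flt1
- Flt4
- Pecam1
- Tek
- Vcam1
- Vegfa
- Vwf
- Dcx
- Eno2
- L1cam
- Map2
- Mapt
- Ncam1
- Neurod1
- Nlgn1
- Rbfox3
- Syn1
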