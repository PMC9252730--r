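# HET codes never treated as ligands: water plus common cryo-protectants,
# buffer components and counter-ions. One code per line; '#' comments.
HOH
DOD
WAT
GOL
EDO
PEG
PGE
PG4
MPD
DMS
ACT
FMT
TRS
BME
SO4
PO4
NO3
CO3
CL
BR
IOD
NA
K
LI
CS
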