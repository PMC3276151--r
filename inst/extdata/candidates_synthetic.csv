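name,chr,pos
CG4766,X,1.5
Nep1,X,5.0
lz,X,27.7
FucTC,X,50.0
al,2,0.4
msl-2,2,9.0
salr,2,16.0
CG4267,2,20.0
CG31686,2,25.0
Wnt2,2,30.0
ap,2,55.4
Poxn,2,67.0
toe,3,1.0
eyg,3,35.0
caup,3,40.0
dsx,3,48.1
abd-A,3,58.8
bab1,3,61.0
Ctr1B,3,70.0
bnl,3,85.0
AP-2,3,95.0
Dr,3,99.2
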