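classification,SB,SD,RC,DS,HC,FC,LC,nDTLB,CLC,Pond,River,Lake,CS
SB,12,0,0,0,2,2,0,0,2,0,1,0,0
SD,3,12,0,0,2,0,0,0,0,0,0,0,0
RC,0,0,4,0,0,0,1,0,0,0,0,0,0
DS,0,0,0,50,19,4,0,0,0,0,0,0,0
HC,0,0,0,35,215,30,22,2,0,0,0,0,0
FC,0,0,0,0,11,32,3,0,0,0,0,0,0
LC,0,0,1,6,34,11,152,5,7,0,0,2,0
nDTLB,0,0,0,0,3,0,16,53,1,0,1,2,0
CLC,0,0,0,0,0,0,2,2,15,0,0,2,0
Pond,0,0,0,0,0,0,0,0,0,18,0,0,0
River,2,0,0,0,0,0,0,2,2,0,10,0,0
Lake,0,0,0,0,0,0,1,1,0,0,0,156,0
CS,0,0,0,0,0,0,0,0,0,0,0,1,28
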