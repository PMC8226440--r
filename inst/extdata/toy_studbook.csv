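id,sire,dam,sex,birth,flock
A1,,,M,2005,North
A2,,,F,2006,North
A3,,,M,2006,South
A4,,,F,2005,South
B1,A1,A2,M,2009,North
B2,A1,A2,F,2010,North
B3,A3,A4,F,2010,South
B4,A3,A4,M,2011,South
C1,B1,B3,M,2014,North
C2,B1,B3,F,2014,North
C3,B4,B2,F,2015,North
C4,B1,B2,M,2015,North
C5,B4,B3,F,2014,South
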