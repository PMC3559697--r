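sample,group,classA,classB,classC,classD,classE,classF,classG,age,sex
SZ1,SZ,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,74,M
SZ2,SZ,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,65,M
SZ3,SZ,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,82,M
SZ4,SZ,FALSE,TRUE,TRUE,FALSE,FALSE,FALSE,FALSE,77,M
SZ5,SZ,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,FALSE,84,M
SZ6,SZ,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,FALSE,79,M
SZ7,SZ,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,TRUE,63,M
SZ8,SZ,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,35,M
BD1,BD,FALSE,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,40,M
BD2,BD,FALSE,TRUE,TRUE,TRUE,FALSE,FALSE,FALSE,38,M
BD3,BD,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,50,M
BD4,BD,FALSE,TRUE,TRUE,FALSE,FALSE,TRUE,FALSE,74,M
BD5,BD,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE,73,M
BD6,BD,FALSE,TRUE,FALSE,TRUE,FALSE,FALSE,FALSE,70,M
C1,C,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,67,M
C2,C,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,37,M
C3,C,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,38,M
C4,C,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,50,M
C5,C,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,40,M
C6,C,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,68,M
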