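condition_class,condition_value,n,n1,p1_printed
sx,"-Log(IC50) (nM)",2438,2148,0.88
sx,"EC50 (nM)",2149,1975,0.92
sx,"Ki (nM)",1501,1418,0.94
sx,"Selectivity",486,102,0.21
sx,"Dopamine release (%)",299,130,0.43
sx,"Activity (%)",222,105,0.47
sx,"Inhibition (%)",193,93,0.48
sx,"Activity (nM)",98,93,0.95
sx,"NO formation (%)",18,6,0.33
sx,"%max (%)",20,4,0.20
ot,"R. norvegicus",2852,1998,0.70
ot,"H. sapiens",4854,4090,0.84
ot,"M. musculus",241,173,0.72
ot,"B. taurus",77,21,0.27
ot,"H. virescens",5,5,1.00
te,"Q9UGM1",403,254,0.63
te,"P29476",859,562,0.65
te,"P35228",128,32,0.25
te,"P19838",1000,923,0.92
te,"P29474",88,18,0.20
au,"1613870",2000,1846,0.92
au,"832611",646,646,1.00
au,"792863",299,130,0.43
au,"899883",114,99,0.87
au,"829510",50,50,1.00
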