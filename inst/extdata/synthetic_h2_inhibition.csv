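"compound","conc_mM","replicate","value"
"KSeCN",0,1,2201.66415453652
"KSCN",0,1,2232.55632007289
"KSeCN",0.5,1,1899.66659459177
"KSCN",0.5,1,1976.03026092958
"KSeCN",1,1,1899.60759293608
"KSCN",1,1,2134.57955472474
"KSeCN",5,1,1178.71152516641
"KSCN",5,1,1690.56622027792
"KSeCN",10,1,889.153827042018
"KSCN",10,1,1331.24457889298
"KSeCN",0,2,2250.6223578891
"KSCN",0,2,2183.88269677061
"KSeCN",0.5,2,2081.75826576352
"KSCN",0.5,2,2061.86190286171
"KSeCN",1,2,1932.59561743377
"KSCN",1,2,2104.93789990178
"KSeCN",5,2,1132.13755463674
"KSCN",5,2,1630.40259183417
"KSeCN",10,2,856.973942330357
"KSCN",10,2,1290.80629561457
"KSeCN",0,3,2002.90384912928
"KSCN",0,3,2201.0071093086
"KSeCN",0.5,3,2138.49842979894
"KSCN",0.5,3,2038.76643881029
"KSeCN",1,3,1886.26872703509
"KSCN",1,3,2043.99464339705
"KSeCN",5,3,1208.91878085968
"KSCN",5,3,1740.07792048812
"KSeCN",10,3,787.833016641955
"KSCN",10,3,1220.79367849242
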