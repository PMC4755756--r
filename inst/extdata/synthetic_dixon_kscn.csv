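"substrate","inhibitor","replicate","velocity","compound"
20,0,1,74.7947660655812,"KSCN"
30,0,1,99.3500454910661,"KSCN"
40,0,1,119.153259360639,"KSCN"
60,0,1,149.945990486758,"KSCN"
100,0,1,192.651190673516,"KSCN"
500,0,1,268.127402780597,"KSCN"
20,1000,1,69.8797823193573,"KSCN"
30,1000,1,95.2280621996244,"KSCN"
40,1000,1,114.80157059733,"KSCN"
60,1000,1,144.888960957426,"KSCN"
100,1000,1,181.121550641539,"KSCN"
500,1000,1,266.214527834743,"KSCN"
20,2000,1,66.2710214477936,"KSCN"
30,2000,1,89.9624982626096,"KSCN"
40,2000,1,110.857099907497,"KSCN"
60,2000,1,140.47304936092,"KSCN"
100,2000,1,174.356202620082,"KSCN"
500,2000,1,261.381638512694,"KSCN"
20,3000,1,64.3107134531551,"KSCN"
30,3000,1,86.1161024385482,"KSCN"
40,3000,1,103.811505386404,"KSCN"
60,3000,1,134.479900612932,"KSCN"
100,3000,1,173.013753920113,"KSCN"
500,3000,1,261.872849978711,"KSCN"
20,4000,1,61.759408894895,"KSCN"
30,4000,1,82.0464692030892,"KSCN"
40,4000,1,102.035328043489,"KSCN"
60,4000,1,129.832371718573,"KSCN"
100,4000,1,168.443152268469,"KSCN"
500,4000,1,257.182877075231,"KSCN"
20,0,2,74.8991862433911,"KSCN"
30,0,2,99.4771431204289,"KSCN"
40,0,2,118.249376989232,"KSCN"
60,0,2,147.11974600664,"KSCN"
100,0,2,187.309619055152,"KSCN"
500,0,2,268.546632119522,"KSCN"
20,1000,2,70.0225328327345,"KSCN"
30,1000,2,94.6348118466209,"KSCN"
40,1000,2,115.871351933491,"KSCN"
60,1000,2,146.43905962563,"KSCN"
100,1000,2,178.885277165152,"KSCN"
500,1000,2,264.175137318066,"KSCN"
20,2000,2,66.5266032447355,"KSCN"
30,2000,2,87.515563139349,"KSCN"
40,2000,2,110.02160636941,"KSCN"
60,2000,2,137.59261918701,"KSCN"
100,2000,2,177.676198237949,"KSCN"
500,2000,2,261.534167829863,"KSCN"
20,3000,2,63.9893396217774,"KSCN"
30,3000,2,87.1824415142231,"KSCN"
40,3000,2,105.930726127986,"KSCN"
60,3000,2,134.463232500773,"KSCN"
100,3000,2,172.068660404748,"KSCN"
500,3000,2,258.065973640772,"KSCN"
20,4000,2,60.3636479791013,"KSCN"
30,4000,2,83.3718540424003,"KSCN"
40,4000,2,102.022439268417,"KSCN"
60,4000,2,128.141210614238,"KSCN"
100,4000,2,163.928968554656,"KSCN"
500,4000,2,258.190075479589,"KSCN"
20,0,3,75.854977916746,"KSCN"
30,0,3,99.9671654201763,"KSCN"
40,0,3,120.605014280657,"KSCN"
60,0,3,149.863079235569,"KSCN"
100,0,3,187.267181445946,"KSCN"
500,0,3,263.480524515178,"KSCN"
20,1000,3,70.1684528770772,"KSCN"
30,1000,3,93.271651778074,"KSCN"
40,1000,3,114.302526868946,"KSCN"
60,1000,3,143.050375892649,"KSCN"
100,1000,3,180.950749544129,"KSCN"
500,1000,3,263.38618362092,"KSCN"
20,2000,3,66.4042077831566,"KSCN"
30,2000,3,89.3545949101871,"KSCN"
40,2000,3,110.724598169887,"KSCN"
60,2000,3,139.497106544025,"KSCN"
100,2000,3,176.77696455124,"KSCN"
500,2000,3,261.457468255049,"KSCN"
20,3000,3,63.362487691365,"KSCN"
30,3000,3,86.5179605414842,"KSCN"
40,3000,3,104.73494110932,"KSCN"
60,3000,3,131.866225598462,"KSCN"
100,3000,3,170.52734366105,"KSCN"
500,3000,3,263.371786419678,"KSCN"
20,4000,3,60.9492894117759,"KSCN"
30,4000,3,82.4360867656244,"KSCN"
40,4000,3,100.985878758877,"KSCN"
60,4000,3,128.625853938498,"KSCN"
100,4000,3,166.312019942822,"KSCN"
500,4000,3,262.434648530993,"KSCN"
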