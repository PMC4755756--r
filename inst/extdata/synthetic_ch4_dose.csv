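"compound","conc_mM","replicate","value"
"KSeCN",0.05,1,1.45609309829507
"KSCN",0.05,1,0.103533561219974
"KSeCN",0.1,1,2.85109127796687
"KSCN",0.1,1,0.165041828096975
"KSeCN",0.2,1,5.60643195958587
"KSCN",0.2,1,0.377014791516877
"KSeCN",0.5,1,9.31236426709571
"KSCN",0.5,1,0.996382852766954
"KSeCN",1,1,10.783438040437
"KSCN",1,1,1.86063965331982
"KSeCN",2,1,9.39535164380043
"KSCN",2,1,3.29691730318083
"KSeCN",5,1,1.08135605079516
"KSCN",5,1,6.34202548839622
"KSeCN",0.05,2,1.65825327815915
"KSCN",0.05,2,0.0995210636778036
"KSeCN",0.1,2,3.02530853093088
"KSCN",0.1,2,0.210636024407313
"KSeCN",0.2,2,5.70857031915775
"KSCN",0.2,2,0.364469114324831
"KSeCN",0.5,2,10.5362423828954
"KSCN",0.5,2,0.979436047159657
"KSeCN",1,2,11.7665317374932
"KSCN",1,2,1.64042976106935
"KSeCN",2,2,9.30791526512597
"KSCN",2,2,3.22983502223012
"KSeCN",5,2,1.16292924628462
"KSCN",5,2,6.97002396352654
"KSeCN",0.05,3,1.57187418267491
"KSCN",0.05,3,0.100507403398709
"KSeCN",0.1,3,2.98985619302973
"KSCN",0.1,3,0.181910235556551
"KSeCN",0.2,3,5.12059610579342
"KSCN",0.2,3,0.38349370066429
"KSeCN",0.5,3,10.4560783664314
"KSCN",0.5,3,0.966540708184657
"KSeCN",1,3,13.2829005832771
"KSCN",1,3,1.93556159718079
"KSeCN",2,3,8.73683446155601
"KSCN",2,3,3.14207120896228
"KSeCN",5,3,1.09463412258081
"KSCN",5,3,6.03356114546866
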