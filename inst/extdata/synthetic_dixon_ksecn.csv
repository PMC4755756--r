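"substrate","inhibitor","replicate","velocity","compound"
20,0,1,75.0997275145458,"KSeCN"
30,0,1,99.0939057921829,"KSeCN"
40,0,1,117.053275441128,"KSeCN"
60,0,1,148.99634931718,"KSeCN"
100,0,1,187.398601504531,"KSeCN"
500,0,1,266.370912964082,"KSeCN"
20,50,1,68.5818627518893,"KSeCN"
30,50,1,92.3518654338694,"KSeCN"
40,50,1,111.812382111067,"KSeCN"
60,50,1,140.126870582184,"KSeCN"
100,50,1,177.987856676419,"KSeCN"
500,50,1,271.779112233719,"KSeCN"
20,100,1,63.0034054044439,"KSeCN"
30,100,1,85.6905638987591,"KSeCN"
40,100,1,105.442620332095,"KSeCN"
60,100,1,135.911330713595,"KSeCN"
100,100,1,173.167641421445,"KSeCN"
500,100,1,258.972464919462,"KSeCN"
20,200,1,54.8959868833669,"KSeCN"
30,200,1,75.4627926446424,"KSeCN"
40,200,1,95.8026504629261,"KSeCN"
60,200,1,121.325943328534,"KSeCN"
100,200,1,157.921526098278,"KSeCN"
500,200,1,255.592721060517,"KSeCN"
20,500,1,38.6039846727828,"KSeCN"
30,500,1,55.0141252189736,"KSeCN"
40,500,1,67.965350579188,"KSeCN"
60,500,1,93.7432032905648,"KSeCN"
100,500,1,128.327687618318,"KSeCN"
500,500,1,237.370751902276,"KSeCN"
20,0,2,75.3720725366871,"KSeCN"
30,0,2,99.9688634932571,"KSeCN"
40,0,2,119.531924256597,"KSeCN"
60,0,2,150.467305217462,"KSeCN"
100,0,2,187.354835273103,"KSeCN"
500,0,2,265.455947247381,"KSeCN"
20,50,2,67.6212296383824,"KSeCN"
30,50,2,92.6366835178858,"KSeCN"
40,50,2,111.47512839127,"KSeCN"
60,50,2,141.290141025474,"KSeCN"
100,50,2,179.522812122527,"KSeCN"
500,50,2,269.225278884778,"KSeCN"
20,100,2,63.6496757159575,"KSeCN"
30,100,2,85.9317893515821,"KSeCN"
40,100,2,103.869144871189,"KSeCN"
60,100,2,131.988949976132,"KSeCN"
100,100,2,169.215199947919,"KSeCN"
500,100,2,259.345080843664,"KSeCN"
20,200,2,55.0112806988924,"KSeCN"
30,200,2,75.6582376339288,"KSeCN"
40,200,2,93.8386811535794,"KSeCN"
60,200,2,122.444922894842,"KSeCN"
100,200,2,156.815910720429,"KSeCN"
500,200,2,259.908990153644,"KSeCN"
20,500,2,39.5691811306927,"KSeCN"
30,500,2,55.5156217654145,"KSeCN"
40,500,2,69.8507846811675,"KSeCN"
60,500,2,93.9565045675647,"KSeCN"
100,500,2,128.941842149622,"KSeCN"
500,500,2,236.888234052033,"KSeCN"
20,0,3,73.416008880918,"KSeCN"
30,0,3,98.4906789298606,"KSeCN"
40,0,3,119.923813911024,"KSeCN"
60,0,3,150.005222986127,"KSeCN"
100,0,3,185.149272741671,"KSeCN"
500,0,3,269.934500009869,"KSeCN"
20,50,3,68.3550300220562,"KSeCN"
30,50,3,91.8106035857692,"KSeCN"
40,50,3,112.393753642938,"KSeCN"
60,50,3,141.401047601898,"KSeCN"
100,50,3,175.823912056311,"KSeCN"
500,50,3,256.400245385408,"KSeCN"
20,100,3,63.2486145238424,"KSeCN"
30,100,3,86.102826019662,"KSeCN"
40,100,3,104.390668575856,"KSeCN"
60,100,3,131.705644161379,"KSeCN"
100,100,3,171.378575205185,"KSeCN"
500,100,3,259.44017582546,"KSeCN"
20,200,3,54.387959243608,"KSeCN"
30,200,3,76.9735113588664,"KSeCN"
40,200,3,93.2321563171492,"KSeCN"
60,200,3,119.828760170685,"KSeCN"
100,200,3,162.845956323804,"KSeCN"
500,200,3,251.249787912737,"KSeCN"
20,500,3,39.1055348722115,"KSeCN"
30,500,3,55.1244698050588,"KSeCN"
40,500,3,69.0282972720256,"KSeCN"
60,500,3,92.7055045380956,"KSeCN"
100,500,3,128.011198328649,"KSeCN"
500,500,3,238.789014880084,"KSeCN"
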