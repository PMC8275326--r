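dataset,algorithm,endpoint,success_pct
CT,TS,height,43
CT,TS,width,9
CT,TS,snr,40
CT,TS,combo1,35
CT,TS,combo2,38
CT,EI,height,35
CT,EI,width,11
CT,EI,snr,69
CT,EI,combo1,40
CT,EI,combo2,38
CT,PI,height,36
CT,PI,width,40
CT,PI,snr,63
CT,PI,combo1,40
CT,PI,combo2,38
CT,UCB,height,42
CT,UCB,width,9
CT,UCB,snr,42
CT,UCB,combo1,36
CT,UCB,combo2,29
CT,random,height,25
CT,random,width,19
CT,random,snr,24
CT,random,combo1,23
CT,random,combo2,18
CT-polymer,TS,height,42
CT-polymer,TS,width,50
CT-polymer,TS,snr,41
CT-polymer,TS,combo1,21
CT-polymer,TS,combo2,31
CT-polymer,EI,height,38
CT-polymer,EI,width,54
CT-polymer,EI,snr,53
CT-polymer,EI,combo1,25
CT-polymer,EI,combo2,26
CT-polymer,PI,height,39
CT-polymer,PI,width,56
CT-polymer,PI,snr,52
CT-polymer,PI,combo1,25
CT-polymer,PI,combo2,26
CT-polymer,UCB,height,43
CT-polymer,UCB,width,53
CT-polymer,UCB,snr,37
CT-polymer,UCB,combo1,28
CT-polymer,UCB,combo2,28
CT-polymer,random,height,21
CT-polymer,random,width,31
CT-polymer,random,snr,19
CT-polymer,random,combo1,22
CT-polymer,random,combo2,18
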