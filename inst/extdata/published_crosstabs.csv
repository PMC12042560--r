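region,measure,moaks_score,qmoaks_score,count
cMF,ThMCM,0,0,36
cMF,ThMCM,0,1,20
cMF,ThMCM,0,2,6
cMF,ThMCM,0,3,0
cMF,ThMCM,1,0,35
cMF,ThMCM,1,1,18
cMF,ThMCM,1,2,3
cMF,ThMCM,1,3,0
cMF,ThMCM,2,0,21
cMF,ThMCM,2,1,49
cMF,ThMCM,2,2,89
cMF,ThMCM,2,3,0
cMF,ThMCM,3,0,0
cMF,ThMCM,3,1,1
cMF,ThMCM,3,2,19
cMF,ThMCM,3,3,0
cMT,ThMCM,0,0,92
cMT,ThMCM,0,1,16
cMT,ThMCM,0,2,19
cMT,ThMCM,0,3,0
cMT,ThMCM,1,0,2
cMT,ThMCM,1,1,2
cMT,ThMCM,1,2,2
cMT,ThMCM,1,3,0
cMT,ThMCM,2,0,29
cMT,ThMCM,2,1,25
cMT,ThMCM,2,2,96
cMT,ThMCM,2,3,7
cMT,ThMCM,3,0,0
cMT,ThMCM,3,1,0
cMT,ThMCM,3,2,6
cMT,ThMCM,3,3,1
cMF,dMCM,0,0,0
cMF,dMCM,0,1,205
cMF,dMCM,0,2,10
cMF,dMCM,0,3,0
cMF,dMCM,1,0,0
cMF,dMCM,1,1,35
cMF,dMCM,1,2,0
cMF,dMCM,1,3,0
cMF,dMCM,2,0,0
cMF,dMCM,2,1,36
cMF,dMCM,2,2,11
cMF,dMCM,2,3,0
cMF,dMCM,3,0,0
cMF,dMCM,3,1,0
cMF,dMCM,3,2,0
cMF,dMCM,3,3,0
cMT,dMCM,0,0,81
cMT,dMCM,0,1,145
cMT,dMCM,0,2,7
cMT,dMCM,0,3,0
cMT,dMCM,1,0,6
cMT,dMCM,1,1,14
cMT,dMCM,1,2,15
cMT,dMCM,1,3,0
cMT,dMCM,2,0,1
cMT,dMCM,2,1,9
cMT,dMCM,2,2,19
cMT,dMCM,2,3,0
cMT,dMCM,3,0,0
cMT,dMCM,3,1,0
cMT,dMCM,3,2,0
cMT,dMCM,3,3,0
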