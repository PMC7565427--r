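dataset,n1,n2,pip_random_all,pip_random_lincs,pip_original
CCLE,1600,800,27.3,23.0,16.0
CCLE,800,400,33.5,26.5,16.3
CCLE,400,200,33.5,29.9,14.8
CCLE,200,100,43.5,37.2,17.9
GCSI,1600,800,11.7,14.4,3.4
GCSI,800,400,18.0,18.0,3.0
GCSI,400,200,23.8,22.7,4.0
GCSI,200,100,35.1,32.1,5.6
GDSC,1600,800,15.0,12.2,6.3
GDSC,800,400,15.5,13.0,8.4
GDSC,400,200,19.9,15.3,11.1
GDSC,200,100,24.7,18.1,13.4
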