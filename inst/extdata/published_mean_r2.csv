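dataset,n1,n2,enhanced,random_all,random_lincs,original,descriptors_only
CCLE,1600,800,0.725,0.715,0.716,0.719,0.678
CCLE,800,400,0.724,0.712,0.714,0.717,0.678
CCLE,400,200,0.721,0.710,0.711,0.715,0.678
CCLE,200,100,0.719,0.706,0.708,0.713,0.678
GCSI,1600,800,0.678,0.670,0.669,0.676,0.600
GCSI,800,400,0.678,0.666,0.666,0.675,0.600
GCSI,400,200,0.675,0.661,0.661,0.672,0.600
GCSI,200,100,0.672,0.653,0.654,0.668,0.600
GDSC,1600,800,0.625,0.618,0.619,0.621,0.570
GDSC,800,400,0.624,0.616,0.617,0.619,0.570
GDSC,400,200,0.622,0.614,0.615,0.617,0.570
GDSC,200,100,0.620,0.610,0.612,0.614,0.570
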