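dataset,total,between_ccl,within_ccl,between_drug,within_drug
CCLE,282.97,21.93,261.05,192.60,90.37
GCSI,203.14,22.43,180.71,122.85,80.30
GDSC,3413.74,218.11,3195.64,1954.38,1459.37
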