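idA,idB,kd_nM
P001,P001,1487.2640729248747
P001,P002,5000
P001,P003,146.11120209114551
P001,P004,5000
P001,P006,5000
P001,P010,5000
P001,P011,5000
P001,P012,1749.2518639862146
P002,P002,275.70905676780217
P002,P003,5000
P002,P004,5000
P002,P005,5000
P002,P006,5000
P002,P007,5000
P003,P003,1789.5905060153605
P003,P005,5000
P003,P007,35.22520020818115
P003,P008,5000
P003,P009,5000
P004,P004,4104.09171555438
P004,P006,5000
P004,P007,5000
P004,P009,5000
P004,P010,5000
P004,P012,5000
P005,P005,346.2841752719617
P005,P010,5000
P006,P006,5000
P006,P007,5000
P006,P008,5000
P006,P010,5000
P007,P007,5000
P007,P010,5000
P008,P008,19.404818007283886
P009,P009,5000
P009,P010,5000
P010,P010,1346.4189033490209
P011,P011,232.30870092939335
P011,P012,5000
P012,P012,88.60519062303376
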