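dataset_id,participant_id,SCR,PSR,RAR,HPR
FER02,FER02_001,0.0135,-0.0066,0.8713,38.8791
FER02,FER02_002,-0.14,0.123,-0.8137,-4.908
FER02,FER02_003,0.1914,0.027,1.1902,-59.0359
FER02,FER02_004,-0.062,0.049,-0.384,7.8045
FER02,FER02_005,0.075,0.3009,-0.4926,0.3561
FER02,FER02_006,-0.0787,-0.0218,-1.0377,-0.2516
FER02,FER02_007,-0.2198,-0.1913,-0.6769,-7.1589
FER02,FER02_008,-0.0941,-0.1179,0.6058,2.4461
FER02,FER02_009,0.5205,0.1986,-0.3881,-11.2526
FER02,FER02_010,0.2371,0.0268,-0.3263,22.8558
FSS6B,FSS6B_001,0.0585,0.1083,,
FSS6B,FSS6B_002,0.1164,0.0642,,
FSS6B,FSS6B_003,0.078,0.0141,,
FSS6B,FSS6B_004,0.0291,0.0072,,
FSS6B,FSS6B_005,0.1743,0.0475,,
FSS6B,FSS6B_006,0.1336,0.0239,,
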