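name,platform,q1,q3,rt_min,quant_type,auc_a,auc_b,auc_c,covariate
PE(20:4/20:4),phospholipid,788.5,647.5,2.32,absolute,0.8702,0.8922,0.8805,FALSE
LysoPC(18:2),phospholipid,520.3,184.1,0.62,absolute,0.7845,0.9313,0.8680,FALSE
PC(P-18:0/22:6),phospholipid,818.3,184.1,4.76,absolute,0.8697,0.8544,0.8603,FALSE
C24 Ceramide,sphingolipid,650.5,632.5,10.50,absolute,0.8024,0.9005,0.8584,FALSE
PE(P-18:0/22:6),phospholipid,776.7,385.3,4.64,absolute,0.8841,0.9253,0.8537,FALSE
C10-carnitine,acylcarnitine,316.4,84.9,4.16,absolute,0.8264,0.8564,0.8462,FALSE
PC(18:0/22:6),phospholipid,834.6,184.1,4.14,absolute,0.8335,0.8444,0.8437,FALSE
PE(P-16:0/20:4),phospholipid,724.5,361.2,3.42,relative,0.7809,0.8558,0.8252,FALSE
PC(16:1/16:1),phospholipid,730.5,184.1,2.22,absolute,0.7623,0.8483,0.8212,FALSE
LysoPC(18:3),phospholipid,518.3,184.0,0.54,relative,0.8052,0.8858,0.8188,FALSE
LysoPC(22:6),phospholipid,568.3,184.0,0.58,relative,0.8599,0.9152,0.8092,FALSE
PC(16:0/22:6),phospholipid,806.6,184.1,2.88,absolute,0.8632,0.8523,0.8005,FALSE
PE(P-18:0/18:2),phospholipid,728.6,337.3,5.20,relative,0.8175,0.9000,0.8000,FALSE
PE(P-18:0/20:4),phospholipid,752.7,361.1,4.94,absolute,0.7914,0.9062,0.7989,FALSE
LysoPC(20:2),phospholipid,548.4,184.0,0.71,relative,0.7873,0.8941,0.7980,FALSE
PC(18:1/18:1),phospholipid,786.6,184.1,4.38,absolute,0.7518,0.9159,0.7910,FALSE
PC(14:0/14:0),phospholipid,678.5,184.1,1.94,absolute,0.7504,0.7865,0.7793,FALSE
PC(18:0/18:0),phospholipid,790.6,184.1,7.91,absolute,0.8150,0.9030,0.7739,FALSE
PC(16:0/18:2),phospholipid,758.6,184.1,3.20,absolute,0.7531,0.8813,0.7610,FALSE
LysoPC(20:3),phospholipid,546.4,184.0,0.64,relative,0.7539,0.8567,0.7563,FALSE
CA19-9,,,,,,0.7571,0.7356,0.7489,TRUE
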