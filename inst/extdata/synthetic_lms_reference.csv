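"sex","agemos","L","M","S"
"M",102,-2.45,16.4,0.135
"M",102.5,-2.44775,16.4141,0.1353
"M",103,-2.4455,16.4284,0.1356
"M",103.5,-2.44325,16.4429,0.1359
"M",104,-2.441,16.4576,0.1362
"M",104.5,-2.43875,16.4725,0.1365
"M",105,-2.4365,16.4876,0.1368
"M",105.5,-2.43425,16.5029,0.1371
"M",106,-2.432,16.5184,0.1374
"M",106.5,-2.42975,16.5341,0.1377
"M",107,-2.4275,16.55,0.138
"M",107.5,-2.42525,16.5661,0.1383
"M",108,-2.423,16.5824,0.1386
"M",108.5,-2.42075,16.5989,0.1389
"M",109,-2.4185,16.6156,0.1392
"M",109.5,-2.41625,16.6325,0.1395
"M",110,-2.414,16.6496,0.1398
"M",110.5,-2.41175,16.6669,0.1401
"M",111,-2.4095,16.6844,0.1404
"M",111.5,-2.40725,16.7021,0.1407
"M",112,-2.405,16.72,0.141
"M",112.5,-2.40275,16.7381,0.1413
"M",113,-2.4005,16.7564,0.1416
"M",113.5,-2.39825,16.7749,0.1419
"M",114,-2.396,16.7936,0.1422
"M",114.5,-2.39375,16.8125,0.1425
"M",115,-2.3915,16.8316,0.1428
"M",115.5,-2.38925,16.8509,0.1431
"M",116,-2.387,16.8704,0.1434
"M",116.5,-2.38475,16.8901,0.1437
"M",117,-2.3825,16.91,0.144
"M",117.5,-2.38025,16.9301,0.1443
"M",118,-2.378,16.9504,0.1446
"M",118.5,-2.37575,16.9709,0.1449
"M",119,-2.3735,16.9916,0.1452
"M",119.5,-2.37125,17.0125,0.1455
"M",120,-2.369,17.0336,0.1458
"M",120.5,-2.36675,17.0549,0.1461
"M",121,-2.3645,17.0764,0.1464
"M",121.5,-2.36225,17.0981,0.1467
"M",122,-2.36,17.12,0.147
"M",122.5,-2.35775,17.1421,0.1473
"M",123,-2.3555,17.1644,0.1476
"M",123.5,-2.35325,17.1869,0.1479
"M",124,-2.351,17.2096,0.1482
"M",124.5,-2.34875,17.2325,0.1485
"M",125,-2.3465,17.2556,0.1488
"M",125.5,-2.34425,17.2789,0.1491
"M",126,-2.342,17.3024,0.1494
"M",126.5,-2.33975,17.3261,0.1497
"M",127,-2.3375,17.35,0.15
"M",127.5,-2.33525,17.3741,0.1503
"M",128,-2.333,17.3984,0.1506
"M",128.5,-2.33075,17.4229,0.1509
"M",129,-2.3285,17.4476,0.1512
"M",129.5,-2.32625,17.4725,0.1515
"M",130,-2.324,17.4976,0.1518
"M",130.5,-2.32175,17.5229,0.1521
"M",131,-2.3195,17.5484,0.1524
"M",131.5,-2.31725,17.5741,0.1527
"M",132,-2.315,17.6,0.153
"M",132.5,-2.31275,17.6261,0.1533
"M",133,-2.3105,17.6524,0.1536
"M",133.5,-2.30825,17.6789,0.1539
"M",134,-2.306,17.7056,0.1542
"M",134.5,-2.30375,17.7325,0.1545
"M",135,-2.3015,17.7596,0.1548
"M",135.5,-2.29925,17.7869,0.1551
"M",136,-2.297,17.8144,0.1554
"M",136.5,-2.29475,17.8421,0.1557
"M",137,-2.2925,17.87,0.156
"M",137.5,-2.29025,17.8981,0.1563
"M",138,-2.288,17.9264,0.1566
"F",102,-2.2,16.2,0.14
"F",102.5,-2.198,16.21513,0.140275
"F",103,-2.196,16.2305,0.14055
"F",103.5,-2.194,16.24612,0.140825
"F",104,-2.192,16.262,0.1411
"F",104.5,-2.19,16.27812,0.141375
"F",105,-2.188,16.2945,0.14165
"F",105.5,-2.186,16.31113,0.141925
"F",106,-2.184,16.328,0.1422
"F",106.5,-2.182,16.34512,0.142475
"F",107,-2.18,16.3625,0.14275
"F",107.5,-2.178,16.38012,0.143025
"F",108,-2.176,16.398,0.1433
"F",108.5,-2.174,16.41613,0.143575
"F",109,-2.172,16.4345,0.14385
"F",109.5,-2.17,16.45312,0.144125
"F",110,-2.168,16.472,0.1444
"F",110.5,-2.166,16.49112,0.144675
"F",111,-2.164,16.5105,0.14495
"F",111.5,-2.162,16.53012,0.145225
"F",112,-2.16,16.55,0.1455
"F",112.5,-2.158,16.57013,0.145775
"F",113,-2.156,16.5905,0.14605
"F",113.5,-2.154,16.61112,0.146325
"F",114,-2.152,16.632,0.1466
"F",114.5,-2.15,16.65312,0.146875
"F",115,-2.148,16.6745,0.14715
"F",115.5,-2.146,16.69613,0.147425
"F",116,-2.144,16.718,0.1477
"F",116.5,-2.142,16.74012,0.147975
"F",117,-2.14,16.7625,0.14825
"F",117.5,-2.138,16.78513,0.148525
"F",118,-2.136,16.808,0.1488
"F",118.5,-2.134,16.83112,0.149075
"F",119,-2.132,16.8545,0.14935
"F",119.5,-2.13,16.87812,0.149625
"F",120,-2.128,16.902,0.1499
"F",120.5,-2.126,16.92612,0.150175
"F",121,-2.124,16.9505,0.15045
"F",121.5,-2.122,16.97512,0.150725
"F",122,-2.12,17,0.151
"F",122.5,-2.118,17.02512,0.151275
"F",123,-2.116,17.0505,0.15155
"F",123.5,-2.114,17.07612,0.151825
"F",124,-2.112,17.102,0.1521
"F",124.5,-2.11,17.12813,0.152375
"F",125,-2.108,17.1545,0.15265
"F",125.5,-2.106,17.18112,0.152925
"F",126,-2.104,17.208,0.1532
"F",126.5,-2.102,17.23512,0.153475
"F",127,-2.1,17.2625,0.15375
"F",127.5,-2.098,17.29012,0.154025
"F",128,-2.096,17.318,0.1543
"F",128.5,-2.094,17.34612,0.154575
"F",129,-2.092,17.3745,0.15485
"F",129.5,-2.09,17.40312,0.155125
"F",130,-2.088,17.432,0.1554
"F",130.5,-2.086,17.46112,0.155675
"F",131,-2.084,17.4905,0.15595
"F",131.5,-2.082,17.52012,0.156225
"F",132,-2.08,17.55,0.1565
"F",132.5,-2.078,17.58012,0.156775
"F",133,-2.076,17.6105,0.15705
"F",133.5,-2.074,17.64112,0.157325
"F",134,-2.072,17.672,0.1576
"F",134.5,-2.07,17.70312,0.157875
"F",135,-2.068,17.7345,0.15815
"F",135.5,-2.066,17.76612,0.158425
"F",136,-2.064,17.798,0.1587
"F",136.5,-2.062,17.83012,0.158975
"F",137,-2.06,17.8625,0.15925
"F",137.5,-2.058,17.89512,0.159525
"F",138,-2.056,17.928,0.1598
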