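time_s,r1,r2,r3
0,100.723989481158,101.219828014219,97.2736570091515
300,122.89479705037,117.340343166494,119.942254942639
600,206.576109580492,207.203894357629,209.375566321171
900,419.994679298439,417.100896342298,431.843370571158
1200,804.11403246519,831.083685829338,786.010586588527
1500,1080.07312830167,1047.64499431818,1043.04481567199
1800,1099.26965785975,1167.56174904927,1043.96969913289
2100,1078.6101989882,1154.78115226583,1132.04622439895
2400,993.40813866314,1071.42796650707,1022.23308901735
2700,1099.6535079123,1049.65109497573,1194.82269737325
3000,1106.579435267,1165.45427772315,1143.98779793778
3300,1060.13490838306,1106.28771168186,1092.31834074709
3600,1142.63290625436,1055.50877369798,1082.73415592015
3900,1088.93620905582,1118.43929645829,1075.70536686864
4200,1111.18587394007,1115.71545900798,1039.11128442198
4500,1089.92121623281,990.633828412415,1102.5622707952
4800,1101.84949424925,1111.2560541252,1253.05293483805
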