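temp_c,salinity,ph_nbs,alk_umol_l,po4_umol_l,sioh4_umol_l,pco2_uatm,dic_umol_l,k0_mol_l_atm
10.0,0.0,7.0,1800.0,2.84,141.91,9758.908914,2322.313304,0.053661313
10.0,0.0,7.0,3000.0,2.84,141.91,16267.663978,3871.192243,0.053661313
10.0,0.0,7.0,6000.0,2.84,141.91,32539.551639,7743.38959,0.053661313
10.0,0.0,8.0,1800.0,2.84,141.91,968.856072,1842.878631,0.053661313
10.0,0.0,8.0,3000.0,2.84,141.91,1615.951868,3073.731229,0.053661313
10.0,0.0,8.0,6000.0,2.84,141.91,3233.691355,6150.862722,0.053661313
10.0,0.0,9.0,1800.0,2.84,141.91,91.079392,1737.492073,0.053661313
10.0,0.0,9.0,3000.0,2.84,141.91,152.23745,2904.184556,0.053661313
10.0,0.0,9.0,6000.0,2.84,141.91,305.132596,5820.915764,0.053661313
10.0,5.0,7.0,1800.0,2.84,141.91,6996.360263,2161.647487,0.052340203
10.0,5.0,7.0,3000.0,2.84,141.91,11666.354165,3604.523526,0.052340203
10.0,5.0,7.0,6000.0,2.84,141.91,23341.338919,7211.713623,0.052340203
10.0,5.0,8.0,1800.0,2.84,141.91,681.552611,1805.112654,0.052340203
10.0,5.0,8.0,3000.0,2.84,141.91,1137.924971,3013.828622,0.052340203
10.0,5.0,8.0,6000.0,2.84,141.91,2278.855874,6035.618543,0.052340203
10.0,5.0,9.0,1800.0,2.84,141.91,54.444578,1579.21969,0.052340203
10.0,5.0,9.0,3000.0,2.84,141.91,91.621777,2657.581725,0.052340203
10.0,5.0,9.0,6000.0,2.84,141.91,184.564776,5353.486811,0.052340203
10.0,18.0,7.0,1800.0,2.84,141.91,5635.342529,2066.57448,0.049055544
10.0,18.0,7.0,3000.0,2.84,141.91,9401.50544,3447.689491,0.049055544
10.0,18.0,7.0,6000.0,2.84,141.91,18816.912719,6900.477019,0.049055544
10.0,18.0,8.0,1800.0,2.84,141.91,528.591053,1750.990049,0.049055544
10.0,18.0,8.0,3000.0,2.84,141.91,885.728226,2934.028681,0.049055544
10.0,18.0,8.0,6000.0,2.84,141.91,1778.571159,5891.625259,0.049055544
10.0,18.0,9.0,1800.0,2.84,141.91,32.716032,1353.574819,0.049055544
10.0,18.0,9.0,3000.0,2.84,141.91,56.255045,2327.464768,0.049055544
10.0,18.0,9.0,6000.0,2.84,141.91,115.102577,4762.189642,0.049055544
10.0,35.0,7.0,1800.0,2.84,141.91,4995.080802,2008.726063,0.045069224
10.0,35.0,7.0,3000.0,2.84,141.91,8340.11701,3353.901782,0.045069224
10.0,35.0,7.0,6000.0,2.84,141.91,16702.707532,6716.841082,0.045069224
10.0,35.0,8.0,1800.0,2.84,141.91,448.962329,1690.785303,0.045069224
10.0,35.0,8.0,3000.0,2.84,141.91,757.619894,2853.184996,0.045069224
10.0,35.0,8.0,6000.0,2.84,141.91,1529.263805,5759.184229,0.045069224
10.0,35.0,9.0,1800.0,2.84,141.91,22.178185,1159.345761,0.045069224
10.0,35.0,9.0,3000.0,2.84,141.91,39.59021,2069.544589,0.045069224
10.0,35.0,9.0,6000.0,2.84,141.91,83.120273,4345.041658,0.045069224
20.0,0.0,7.0,1800.0,2.84,141.91,11078.3167,2231.516192,0.039098765
20.0,0.0,7.0,3000.0,2.84,141.91,18467.462524,3719.919079,0.039098765
20.0,0.0,7.0,6000.0,2.84,141.91,36940.327084,7440.926295,0.039098765
20.0,0.0,8.0,1800.0,2.84,141.91,1097.624253,1831.446082,0.039098765
20.0,0.0,8.0,3000.0,2.84,141.91,1830.999011,3055.121966,0.039098765
20.0,0.0,8.0,6000.0,2.84,141.91,3664.435906,6114.311675,0.039098765
20.0,0.0,9.0,1800.0,2.84,141.91,101.258569,1716.032436,0.039098765
20.0,0.0,9.0,3000.0,2.84,141.91,169.481224,2872.204117,0.039098765
20.0,0.0,9.0,6000.0,2.84,141.91,340.037863,5762.633322,0.039098765
20.0,5.0,7.0,1800.0,2.84,141.91,7994.148377,2099.780037,0.038198392
20.0,5.0,7.0,3000.0,2.84,141.91,13330.994187,3501.580674,0.038198392
20.0,5.0,7.0,6000.0,2.84,141.91,26673.108713,7006.082268,0.038198392
20.0,5.0,8.0,1800.0,2.84,141.91,772.242557,1789.727385,0.038198392
20.0,5.0,8.0,3000.0,2.84,141.91,1289.943465,2989.536286,0.038198392
20.0,5.0,8.0,6000.0,2.84,141.91,2584.195736,5989.058538,0.038198392
20.0,5.0,9.0,1800.0,2.84,141.91,57.852254,1521.688252,0.038198392
20.0,5.0,9.0,3000.0,2.84,141.91,97.690827,2569.562517,0.038198392
20.0,5.0,9.0,6000.0,2.84,141.91,197.28726,5189.24818,0.038198392
20.0,18.0,7.0,1800.0,2.84,141.91,6452.826061,2019.406382,0.035953268
20.0,18.0,7.0,3000.0,2.84,141.91,10767.234848,3369.596912,0.035953268
20.0,18.0,7.0,6000.0,2.84,141.91,21553.256816,6745.073236,0.035953268
20.0,18.0,8.0,1800.0,2.84,141.91,592.440304,1723.220312,0.035953268
20.0,18.0,8.0,3000.0,2.84,141.91,994.192328,2891.789101,0.035953268
20.0,18.0,8.0,6000.0,2.84,141.91,1998.572388,5813.211076,0.035953268
20.0,18.0,9.0,1800.0,2.84,141.91,32.457614,1267.152204,0.035953268
20.0,18.0,9.0,3000.0,2.84,141.91,56.25622,2196.254855,0.035953268
20.0,18.0,9.0,6000.0,2.84,141.91,115.752734,4519.011482,0.035953268
20.0,35.0,7.0,1800.0,2.84,141.91,5715.070914,1968.547864,0.033215232
20.0,35.0,7.0,3000.0,2.84,141.91,9545.962296,3288.092828,0.033215232
20.0,35.0,7.0,6000.0,2.84,141.91,19123.19075,6586.95524,0.033215232
20.0,35.0,8.0,1800.0,2.84,141.91,495.587012,1648.531661,0.033215232
20.0,35.0,8.0,3000.0,2.84,141.91,839.015425,2790.919574,0.033215232
20.0,35.0,8.0,6000.0,2.84,141.91,1697.586457,5646.889355,0.033215232
20.0,35.0,9.0,1800.0,2.84,141.91,20.806266,1062.21548,0.033215232
20.0,35.0,9.0,3000.0,2.84,141.91,37.679974,1923.663389,0.033215232
20.0,35.0,9.0,6000.0,2.84,141.91,79.864245,4077.283161,0.033215232
30.0,0.0,7.0,1800.0,2.84,141.91,12783.108051,2179.389358,0.029828619
30.0,0.0,7.0,3000.0,2.84,141.91,21309.856758,3633.112921,0.029828619
30.0,0.0,7.0,6000.0,2.84,141.91,42626.728526,7267.42183,0.029828619
30.0,0.0,8.0,1800.0,2.84,141.91,1263.765928,1823.562186,0.029828619
30.0,0.0,8.0,3000.0,2.84,141.91,2108.614429,3042.643777,0.029828619
30.0,0.0,8.0,6000.0,2.84,141.91,4220.735681,6090.347754,0.029828619
30.0,0.0,9.0,1800.0,2.84,141.91,114.268948,1692.663982,0.029828619
30.0,0.0,9.0,3000.0,2.84,141.91,191.651184,2838.92574,0.029828619
30.0,0.0,9.0,6000.0,2.84,141.91,385.106776,5704.580136,0.029828619
30.0,5.0,7.0,1800.0,2.84,141.91,9273.891294,2064.124441,0.029204028
30.0,5.0,7.0,3000.0,2.84,141.91,15466.260921,3442.383156,0.029204028
30.0,5.0,7.0,6000.0,2.84,141.91,30947.184989,6888.029943,0.029204028
30.0,5.0,8.0,1800.0,2.84,141.91,887.800317,1775.99874,0.029204028
30.0,5.0,8.0,3000.0,2.84,141.91,1483.936206,2968.537837,0.029204028
30.0,5.0,8.0,6000.0,2.84,141.91,2974.275929,5949.88558,0.029204028
30.0,5.0,9.0,1800.0,2.84,141.91,62.268051,1463.075031,0.029204028
30.0,5.0,9.0,3000.0,2.84,141.91,105.684737,2483.210868,0.029204028
30.0,5.0,9.0,6000.0,2.84,141.91,214.226454,5033.550458,0.029204028
30.0,18.0,7.0,1800.0,2.84,141.91,7486.528772,1991.281259,0.027640619
30.0,18.0,7.0,3000.0,2.84,141.91,12494.857796,3323.406203,0.027640619
30.0,18.0,7.0,6000.0,2.84,141.91,25015.680356,6653.718563,0.027640619
30.0,18.0,8.0,1800.0,2.84,141.91,671.505376,1695.158493,0.027640619
30.0,18.0,8.0,3000.0,2.84,141.91,1129.043494,2850.174752,0.027640619
30.0,18.0,8.0,6000.0,2.84,141.91,2272.888789,5737.715398,0.027640619
30.0,18.0,9.0,1800.0,2.84,141.91,32.582783,1183.783576,0.027640619
30.0,18.0,9.0,3000.0,2.84,141.91,57.122821,2075.361592,0.027640619
30.0,18.0,9.0,6000.0,2.84,141.91,118.472914,4304.306633,0.027640619
30.0,35.0,7.0,1800.0,2.84,141.91,6608.820172,1943.119054,0.025721746
30.0,35.0,7.0,3000.0,2.84,141.91,11044.122986,3247.182591,0.025721746
30.0,35.0,7.0,6000.0,2.84,141.91,22132.380022,6507.341433,0.025721746
30.0,35.0,8.0,1800.0,2.84,141.91,550.953794,1604.389571,0.025721746
30.0,35.0,8.0,3000.0,2.84,141.91,936.53073,2727.198093,0.025721746
30.0,35.0,8.0,6000.0,2.84,141.91,1900.47307,5534.219398,0.025721746
30.0,35.0,9.0,1800.0,2.84,141.91,19.683895,968.869714,0.025721746
30.0,35.0,9.0,3000.0,2.84,141.91,36.399867,1791.653964,0.025721746
30.0,35.0,9.0,6000.0,2.84,141.91,78.189797,3848.614586,0.025721746
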