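site,forest,ag,embed,mf,imperv
site_01,58.3,2.8,58.6,43514,1.13
site_02,38.1,4.2,22.4,40278,1.08
site_03,106.9,21.2,48.1,11963,0.96
site_04,52.4,5.2,54.1,27020,2.29
site_05,48.3,2.6,66.9,27028,0.69
site_06,79.9,16,20.8,14956,0
site_07,68.4,13.3,12.1,6930,0
site_08,79.3,6,63,4129,1.58
site_09,48.3,11.9,55.1,71430,0.38
site_10,69.5,0,43,33245,2.14
site_11,56.1,14.9,31.6,29065,0.78
site_12,49,0.4,68,29795,6.23
site_13,46.7,1.9,33.1,11623,4.72
site_14,40.6,15.1,15.6,5955,1.1
site_15,56.4,14.1,16,12094,6.5
site_16,72.7,20.6,37.9,20339,2.67
site_17,72.1,11.6,65,24766,5.62
site_18,57,32.4,73.1,38816,9.01
site_19,46,19.8,66.8,49021,4.38
site_20,52.4,7.8,65.5,13621,2.92
site_21,57.9,23.3,62,27262,3.42
site_22,60.3,17.7,47.8,127526,0.97
site_23,54.4,14.5,22.9,62634,3.76
site_24,83,16.9,73.6,1738,2.94
site_25,65.1,3.7,66.9,12293,0.95
site_26,65.9,19.8,58.1,39653,5.17
site_27,59.6,6.2,39.5,65664,4.05
site_28,57.7,20.3,20.3,44844,4.83
site_29,71.8,10.3,61.6,24076,3.53
site_30,32.8,18.4,77.3,282507,4.62
site_31,36.1,13.1,70.6,105992,4.1
site_32,72.6,9.7,37.6,13991,2.64
site_33,64.6,12.8,36.1,14649,5.01
site_34,86.2,9.6,76.7,26580,5.82
site_35,54.2,19.5,15.2,8948,1.43
site_36,49.6,29.3,22,76720,2.74
site_37,71.4,16.2,67.1,15548,4.89
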