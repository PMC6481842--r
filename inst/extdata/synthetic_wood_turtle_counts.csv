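site,occ_1,occ_2,occ_3
site_01,0,7,0
site_02,3,3,2
site_03,7,6,6
site_04,3,6,0
site_05,3,5,0
site_06,5,0,3
site_07,9,7,6
site_08,0,11,8
site_09,0,7,3
site_10,8,4,9
site_11,6,8,6
site_12,6,2,1
site_13,7,2,6
site_14,10,6,5
site_15,6,6,4
site_16,0,5,7
site_17,7,6,4
site_18,0,0,0
site_19,0,0,0
site_20,0,0,0
site_21,0,0,0
site_22,0,0,0
site_23,0,0,0
site_24,0,0,0
site_25,0,0,0
site_26,0,0,0
site_27,0,0,0
site_28,0,0,0
site_29,0,0,0
site_30,0,0,0
site_31,0,0,0
site_32,0,0,0
site_33,0,0,0
site_34,0,0,0
site_35,0,0,0
site_36,0,0,0
site_37,0,0,0
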