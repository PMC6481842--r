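site,occ_1,occ_2,occ_3
site_01,0,1,1
site_02,1,0,1
site_03,1,1,1
site_04,1,0,0
site_05,1,1,1
site_06,0,0,1
site_07,0,1,0
site_08,1,1,1
site_09,0,0,1
site_10,0,1,0
site_11,0,1,0
site_12,1,1,1
site_13,1,0,1
site_14,0,0,0
site_15,0,0,0
site_16,0,0,0
site_17,0,0,0
site_18,0,0,1
site_19,0,0,1
site_20,1,1,1
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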