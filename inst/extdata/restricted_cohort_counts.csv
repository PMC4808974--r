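community_type,tertile_group,n,preterm,sga,low_apgar,overall_t1,overall_t23,ndvi_mean,ndvi_sd
city,T1,927,127,126,17,927,0,0.39,0.04
city,T23,1636,195,180,41,889,747,0.50,0.05
borough,T1,1253,117,109,26,1253,0,0.44,0.04
borough,T23,2544,297,237,39,10,2534,0.57,0.05
township,T1,2249,248,210,42,1195,1054,0.48,0.05
township,T23,4212,465,352,88,0,4212,0.62,0.05
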