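analyte,pretreatment,n_lv,r2_c,rmsec,r2_p,rmsep,rpd,r2_f
fat,None,6,0.955,0.482,0.967,0.431,5.34,
fat,MSC,5,0.962,0.443,0.969,0.412,5.58,
fat,MC,6,0.975,0.355,0.986,0.276,8.33,
fat,1D,4,0.949,0.512,0.954,0.502,4.58,
fat,2D,5,0.958,0.461,0.961,0.467,4.93,
C12:0,None,8,0.915,0.418,0.917,0.375,3.73,0.253
C14:0,MSC,8,0.947,0.773,0.930,0.803,4.11,0.331
C16:0,MSC + Detrend,8,0.812,1.077,0.877,1.012,2.66,0.269
C16:1,Detrend,8,0.337,0.290,0.345,0.255,1.57,0.156
C18:0,2D,8,0.579,0.638,0.510,0.509,1.96,0.071
C18:1w9,MSC,8,0.922,1.104,0.949,0.756,5.55,0.527
C18:2w6,MSC,8,0.925,1.602,0.931,1.411,3.98,0.568
C18:3w3,MSC,8,0.964,0.713,0.945,0.817,4.90,0.019
SFA,MSC,8,0.948,1.088,0.942,1.081,4.26,0.091
MUFA,MSC,8,0.886,1.371,0.903,1.050,4.00,0.511
PUFA,MSC,8,0.943,1.466,0.878,2.115,3.03,0.282
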