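group,substrate,substrate_pct,wheat_bran_pct,diet_fat_pct
CF5,coconut flour,3.4,96.6,5.0
CF10,coconut flour,23.8,76.2,10.0
CF15,coconut flour,46.2,53.8,15.0
CF20,coconut flour,68.6,31.4,20.0
FSF5,flaxseed flour,1.1,98.9,5.0
FSF10,flaxseed flour,18.7,81.3,10.0
FSF15,flaxseed flour,36.4,63.6,15.0
FSF20,flaxseed flour,54.1,45.9,20.0
GP4,grape pomace,42.5,57.5,4.4
HPF5,hemp protein flour,14.5,85.5,5.3
HPF8,hemp protein flour,71.5,28.5,7.8
RHH4,rose hip hulls,36.4,63.6,3.5
PPF5,pea protein flour,7.8,92.2,5.0
PPF6,pea protein flour,38.6,61.4,6.0
WB,wheat bran,0.0,100.0,4.7
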