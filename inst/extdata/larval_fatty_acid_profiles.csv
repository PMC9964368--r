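group,C12:0,C14:0,C16:0,C16:1,C18:0,C18:1w9,C18:2w6,C18:3w3,SFA,MUFA,PUFA
Start,,3.3,23.0,1.4,4.7,31.3,34.8,1.4,31.0,32.8,36.2
CF5,0.7,4.8,22.2,1.6,2.9,39.8,27.2,0.9,30.6,41.4,28.0
CF10,4.6,12.2,21.4,2.4,3.1,36.1,19.1,1.0,41.4,38.6,20.1
CF15,4.7,12.9,20.1,1.5,2.7,41.2,16.5,0.5,40.4,42.7,16.9
CF20,3.2,11.4,19.2,1.7,3.2,44.8,16.3,0.2,40.0,46.5,16.6
FSF5,0.6,3.3,19.3,2.1,3.5,43.1,25.9,2.1,26.8,45.2,28.0
FSF10,0.6,4.4,19.3,1.9,3.4,40.8,21.3,8.4,27.6,42.7,29.7
FSF15,,,22.2,1.4,4.2,37.1,22.1,13.0,26.3,38.5,35.1
FSF20,0.5,4.2,19.5,1.8,4.0,40.3,19.2,10.5,28.2,42.1,29.7
GP4,0.7,6.4,27.1,2.3,2.9,36.8,22.7,1.1,36.2,39.1,23.8
HPF5,0.7,5.0,22.5,2.2,3.4,34.7,29.5,2.0,31.6,36.4,31.5
HPF8,0.9,4.4,19.2,2.5,2.9,35.7,30.8,3.8,27.3,38.2,34.5
RHH4,0.7,6.1,27.1,2.0,2.8,34.4,25.3,1.4,36.9,36.4,26.7
PPF5,1.0,4.4,23.1,2.3,3.0,35.0,29.8,1.4,31.6,36.9,31.5
PPF6,,5.6,21.4,2.1,6.7,30.5,32.1,1.7,33.6,32.6,33.8
WB,0.8,3.8,21.7,1.6,3.1,37.4,30.3,1.3,29.3,39.1,31.7
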