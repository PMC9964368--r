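group,moisture,protein,fat,carbohydrate,fiber,ash
CF5,12.0,14.9,5.0,44.9,17.6,5.6
CF10,11.2,15.2,10.0,43.3,15.6,4.8
CF15,10.4,15.4,15.0,41.8,13.5,3.9
CF20,9.6,15.7,20.0,40.2,11.5,3.0
FSF5,12.0,15.0,5.0,44.8,17.6,5.7
FSF10,11.2,16.4,10.0,41.3,15.6,5.5
FSF15,10.5,17.8,15.0,37.7,13.7,5.3
FSF20,9.8,19.2,20.0,34.2,11.7,5.1
GP4,11.0,12.0,4.4,51.0,16.7,5.0
HPF5,11.6,20.0,5.3,39.6,18.0,5.5
HPF8,9.9,40.0,7.8,18.4,19.3,4.6
RHH4,12.0,10.8,3.5,51.0,17.0,5.7
PPF5,11.3,20.0,5.0,41.9,16.6,5.3
PPF6,8.4,40.0,6.0,29.5,12.5,3.6
WB,12.0,14.9,4.7,45.0,17.7,5.7
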