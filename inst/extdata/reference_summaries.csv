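analyte,set,minimum,maximum,mean,sd
fat,calibration,7.4,16.2,12.0,2.3
fat,validation,7.3,16.2,12.1,2.3
C12:0,calibration,0.4,4.7,1.2,1.5
C12:0,validation,0.3,4.9,1.1,1.4
C14:0,calibration,3.2,13.4,5.8,3.4
C14:0,validation,3.3,13.0,5.6,3.3
C16:0,calibration,18.8,27.6,21.8,2.5
C16:0,validation,18.5,27.8,22.0,2.7
C16:1,calibration,1.1,2.5,1.9,0.4
C16:1,validation,1.3,2.4,1.8,0.4
C18:0,calibration,2.6,6.8,3.5,1.0
C18:0,validation,2.9,6.5,3.6,1.0
C18:1w9,calibration,27.9,44.8,37.5,4.0
C18:1w9,validation,28.7,45.2,37.3,4.2
C18:2w6,calibration,15.9,39.3,25.3,5.9
C18:2w6,validation,16.0,35.4,25.1,5.6
C18:3w3,calibration,0.1,13.2,3.2,3.8
C18:3w3,validation,0.3,13.5,3.3,4.0
SFA,calibration,25.8,42.0,32.4,4.8
SFA,validation,26.2,41.6,32.2,4.6
MUFA,calibration,28.6,46.6,39.5,4.1
MUFA,validation,30.5,46.3,39.4,4.2
PUFA,calibration,16.2,41.1,28.2,6.2
PUFA,validation,16.4,40.2,28.5,6.4
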