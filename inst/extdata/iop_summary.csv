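group,eye,mean,sd,n
DBA2J,right,16.3,1.9,11
DBA2J,left,16.4,2.6,11
C57BL6J,right,11.4,1.1,12
C57BL6J,left,12.0,1.0,12
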