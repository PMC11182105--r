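metric,group,eye,mean,sd,n
retina_peak,DBA2J,right,1.29,0.32,11
retina_peak,DBA2J,left,1.25,0.26,11
retina_peak,C57BL6J,right,1.65,0.20,12
retina_peak,C57BL6J,left,1.53,0.16,12
retina_integrated,DBA2J,right,0.142,0.042,11
retina_integrated,DBA2J,left,0.145,0.038,11
retina_integrated,C57BL6J,right,0.188,0.028,12
retina_integrated,C57BL6J,left,0.208,0.032,12
choroid_peak,DBA2J,right,5.78,1.38,11
choroid_peak,DBA2J,left,5.79,1.08,11
choroid_peak,C57BL6J,right,8.11,0.71,12
choroid_peak,C57BL6J,left,7.62,0.98,12
choroid_integrated,DBA2J,right,0.637,0.131,11
choroid_integrated,DBA2J,left,0.683,0.144,11
choroid_integrated,C57BL6J,right,0.885,0.090,12
choroid_integrated,C57BL6J,left,0.932,0.108,12
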