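metric,r
retina_peak,0.40
retina_integrated,0.59
choroid_peak,0.54
choroid_integrated,0.65
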