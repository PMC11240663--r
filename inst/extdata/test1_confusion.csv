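labelled,sit,stand,walk
sit,1690,170,5
stand,73,230,30
walk,0,21,278
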