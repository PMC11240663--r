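labelled,sit,stand,walk
sit,7269,352,15
stand,235,346,17
walk,4,135,357
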