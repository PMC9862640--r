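view,tp,tn,fp,fn
top,287,785,67,85
bottom,294,808,51,77
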