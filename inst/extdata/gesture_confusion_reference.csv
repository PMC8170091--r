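truth,hello,toward,horizontal,background
hello,70,0,0,5
toward,0,66,5,4
horizontal,0,6,120,0
background,2,0,0,55
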