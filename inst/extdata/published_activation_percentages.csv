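model,configuration,contact,percent
3093,monopolar,0,50
3093,monopolar,1,35
3093,monopolar,2,50
3093,monopolar,3,60
3093,bipolar,0,50
3093,bipolar,1,40
3889,monopolar,0,50
3889,monopolar,1,50
3889,monopolar,2,50
3889,monopolar,3,55
3889,bipolar,0,50
3889,bipolar,1,50
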