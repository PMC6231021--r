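synapse_id,pre_neuron,post_neuron,x,y,z
A,blue,green,0,0,0
B,blue,green,1000,0,0
C,blue,green,2000,0,0
D,red,orange,3000,0,0
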