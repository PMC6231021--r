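synapse_id,pre_neuron,post_neuron,x,y,z
a,2,1,0,0,0
b,2,4,1000,0,0
c,2,1,2000,0,0
d,3,1,3000,0,0
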