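node,cesd,ptsd,stss,risk,special,family,friend
cesd,0,0.436,0.464,0,0,-0.095,-0.021
ptsd,0.436,0,0.009,0,-0.022,-0.137,0
stss,0.464,0.009,0,0.110,0,0,-0.171
risk,0,0,0.110,0,0,-0.132,-0.190
special,0,-0.022,0,0,0,0.290,0.452
family,-0.095,-0.137,0,-0.132,0.290,0,0.254
friend,-0.021,0,-0.171,-0.190,0.452,0.254,0
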