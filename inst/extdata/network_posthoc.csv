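node,cesd,ptsd,risk,special,family,friend,ext_self_perception,care_self_sacrifice,silencing_self,divided_self
cesd,0,0.397,0,0,-0.082,-0.022,0.281,0,0,0.155
ptsd,0.397,0,0,-0.010,-0.140,0,0.019,-0.043,0.059,0
risk,0,0,0,0,-0.008,-0.185,0,0.168,0,0.014
special,0,-0.010,0,0,0.284,0.446,0,0,0,-0.034
family,-0.082,-0.140,-0.008,0.284,0,0.255,0,-0.021,0,0
friend,-0.022,0,-0.185,0.446,0.255,0,0,0,0,0
ext_self_perception,0.281,0.019,0,0,0,0,0,0.215,0.198,0.292
care_self_sacrifice,0,-0.043,0.168,0,-0.021,0,0.215,0,0.182,0
silencing_self,0,0.059,0,0,0,0,0.198,0.182,0,0.519
divided_self,0.155,0,0.014,-0.034,0,0,0.292,0,0.519,0
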