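metal,medium,rfd,sf
Al,water,1.0000,
As,water,0.0003,1.5
Cr,water,0.0030,
Cd,water,0.0050,
Cu,water,0.0400,
Ni,water,0.0200,
Pb,water,0.0014,
Zn,water,0.3000,
Al,food,0.0005,
As,food,0.0003,1.5
Cr,food,0.0030,
Cd,food,0.0010,
Cu,food,0.0370,
Ni,food,0.0200,
Pb,food,0.0037,
Zn,food,0.3000,
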