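name,composition,density_g_cm3,thickness_cm,straggling_range_cm,lambda_cm
W100,W:100,19.3,6.24,2.62,2.7
W90Cu10,W:90;Cu:10,17.34,6.7,2.85,
W50Cu50,W:50;Cu:50,12.25,8.32,3.66,
Fe100,Fe:100,7.87,11,5,
Ni100,Ni:100,8.9,9.6,4.3,
Cu100,Cu:100,8.96,10,4.5,
Cu59Zn41,Cu:59;Zn:41,8.4,10.6,4.8,
SS304,Fe:69.5;Cr:19;Ni:9.5;Mn:2,7.92,10.8,4.9,
Al100,Al:100,2.7,27,13,
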