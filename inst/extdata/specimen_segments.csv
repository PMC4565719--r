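segment,region,variant,mass_kg,x_cm,y_cm,z_cm,count
Head,head,single,0.213,39.54,-0.05,2.35,1
Neck,neck,max,0.260,32.93,-0.01,1.19,1
Neck,neck,min,0.113,32.93,-0.03,1.82,1
Trunk,trunk,max,2.749,13.24,0.01,0.89,1
Trunk,trunk,min,1.369,11.49,-0.01,1.17,1
Pectoral limb,pectoral,max,0.273,27.09,-8.93,-1.74,2
Pectoral limb,pectoral,min,0.182,27.22,-8.69,-1.73,2
Pelvic limb,pelvic,max,0.447,-0.21,-11.15,-0.10,2
Pelvic limb,pelvic,min,0.255,-0.23,-11.48,-0.15,2
Tail,tail,max,0.549,-11.91,0.00,1.71,1
Tail,tail,min,0.182,-11.58,0.01,2.22,1
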