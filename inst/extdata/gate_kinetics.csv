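channel,gate,v_half,slope,tau_min,tau_max,v_tau,sigma_tau
naf,m,-35.0,5.5,0.05,0.05,-35.0,10.0
naf,h,-47.67,-6.0,0.3,3.0,-50.0,5.0
naf,s,-42.19,-7.0,1500.0,1500.0,-30.0,10.0
nap,m,-54.49,6.2,0.2,0.2,-57.7,10.0
nap,h,-59.42,-5.34,187.64,187.64,-57.0,10.0
nap,s,-10.0,-4.9,5000.0,5000.0,-10.0,10.0
kv2,m,-33.2,9.1,1.61,7.63,-50.84,2.5
kv2,h,-20.0,-10.0,3400.0,3400.0,-20.0,10.0
kv3,m,-26.0,7.8,0.87,0.87,-26.0,6.0
kv3,h,-20.0,-10.0,20.0,20.0,-20.0,10.0
kv4f,m,-45.04,12.5,2.0,2.0,-49.0,6.0
kv4f,h,-83.0,-10.0,15.0,15.0,-83.0,10.0
kv4s,m,-45.04,12.5,2.0,2.0,-49.0,6.0
kv4s,h,-83.0,-10.0,60.0,60.0,-83.0,10.0
kcnq,m,-51.13,19.5,80.0,80.0,-61.0,10.0
hva,m,10.0,5.5,0.4,0.4,-10.0,10.0
hcnf,m,-79.49,-2.0,30.0,400.0,-80.0,-8.0
hcns,m,-91.14,-5.84,100.0,3000.0,-80.0,-8.0
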