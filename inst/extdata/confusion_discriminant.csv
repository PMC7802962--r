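method,true_environment,PaulaCandido.Pulped,SenhoraOliveira.Pulped,Araponga.Pulped,Araponga.Natural
Fisher,PaulaCandido.Pulped,4.400,0.150,0.575,0.375
Fisher,SenhoraOliveira.Pulped,0.225,5.125,0.075,0.075
Fisher,Araponga.Pulped,0.150,0.025,3.625,1.700
Fisher,Araponga.Natural,0.100,0.150,1.650,3.600
Anderson,PaulaCandido.Pulped,4.350,0.075,0.700,0.375
Anderson,SenhoraOliveira.Pulped,0.200,5.050,0.225,0.025
Anderson,Araponga.Pulped,0.150,0.000,3.700,1.650
Anderson,Araponga.Natural,0.100,0.050,1.800,3.550
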