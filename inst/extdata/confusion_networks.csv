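method,true_environment,PaulaCandido.Pulped,SenhoraOliveira.Pulped,Araponga.Pulped,Araponga.Natural
RBF,PaulaCandido.Pulped,5.375,0.050,0.075,0.000
RBF,SenhoraOliveira.Pulped,0.000,5.450,0.050,0.000
RBF,Araponga.Pulped,0.000,0.000,4.375,1.125
RBF,Araponga.Natural,0.025,0.000,0.425,5.050
MLP,PaulaCandido.Pulped,5.375,0.125,0.000,0.000
MLP,SenhoraOliveira.Pulped,0.000,5.500,0.000,0.000
MLP,Araponga.Pulped,0.075,0.000,4.400,1.025
MLP,Araponga.Natural,0.025,0.000,0.400,5.075
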