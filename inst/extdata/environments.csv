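name,site,process,altitude_m,n_individuals
PaulaCandido.Pulped,PaulaCandido,pulped,680,22
SenhoraOliveira.Pulped,SenhoraOliveira,pulped,910,22
Araponga.Pulped,Araponga,pulped,1100,22
Araponga.Natural,Araponga,natural,1100,22
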