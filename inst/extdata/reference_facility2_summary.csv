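substrate,transporter,er_mean,er_sd,n
digoxin,P-gp,1.5,0.4,3
dantrolene,BCRP,2.0,0.7,3
SASP,BCRP,1.4,0.1,3
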