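substrate,transporter,experiment,pe_a2b,pe_b2a,mark
rhodamine123,P-gp,exp1,24.5,127.5,*
rhodamine123,P-gp,exp2,11.6,21.7,**
rhodamine123,P-gp,exp3,35.3,33.0,none
rhodamine123,P-gp,exp4,21.6,20.1,none
hoechst33342,BCRP,exp1,20.3,37.0,*
hoechst33342,BCRP,exp2,8.4,12.6,none
hoechst33342,BCRP,exp3,1.4,3.6,*
hoechst33342,BCRP,exp4,2.4,15.6,*
2-NBDG,Glut1,exp1,56.5,90.8,none
2-NBDG,Glut1,exp2,113.5,114.3,none
2-NBDG,Glut1,exp3,51.9,37.9,*
2-NBDG,Glut1,exp4,44.8,45.1,none
transferrin,TfR,exp1,1.3,1.2,none
transferrin,TfR,exp2,3.5,1.8,**
transferrin,TfR,exp3,3.0,1.7,*
digoxin,P-gp,exp1,41.2,52.9,*
digoxin,P-gp,exp2,45.7,53.6,none
digoxin,P-gp,exp3,48.9,55.5,none
digoxin,P-gp,exp4,17.6,28.1,**
dantrolene,BCRP,exp1,62.9,92.5,**
dantrolene,BCRP,exp2,135.5,368.9,*
dantrolene,BCRP,exp3,98.5,330.4,*
dantrolene,BCRP,exp4,107.3,166.9,none
SASP,BCRP,exp1,40.2,50.1,**
SASP,BCRP,exp2,81.2,84.4,*
SASP,BCRP,exp3,58.8,101.3,**
SASP,BCRP,exp4,25.7,36.4,**
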