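parameter,value
beta_CLN3,-5.69897000433602
alpha_CLN3,-2.47172622283296
deltap_CLN3,-2.79048498545737
beta_CLN2,-5.39794000867204
alpha_CLN2,-2.77275621849694
deltap_CLN2,-2.9402473057907
beta_CLB5,-5.52287874528034
alpha_CLB5,-2.96657624451305
deltap_CLB5,-2.82827354634677
beta_CLB2,-5.69897000433602
alpha_CLB2,-2.82827354634677
deltap_CLB2,-2.91542372206567
beta_SWI4,-5.61978875828839
alpha_SWI4,-2.47172622283296
deltap_SWI4,-2.86966623150499
beta_NDD1,-5.69897000433602
alpha_NDD1,-2.47172622283296
deltap_NDD1,-2.82827354634677
beta_SWI5,-5.69897000433602
alpha_SWI5,-2.47172622283296
deltap_SWI5,-2.89194262621615
beta_HCM1,-5.79588001734407
alpha_HCM1,-2.43033353767473
deltap_HCM1,-2.86966623150499
beta_YOX1,-5.61978875828839
alpha_YOX1,-2.51748371339363
deltap_YOX1,-2.84847693243506
deltam,-2.86966623150499
kappa,-2.86966623150499
K_tx_CLN3,-1.69897000433602
h_tx_CLN3,3.8
K_tx_SWI4,-1.69897000433602
h_tx_SWI4,3.8
K_deg_NDD1,-1.69897000433602
h_deg_NDD1,2
m0_CLN3,-2.30102999566398
p0_CLN3,-2.30102999566398
m0_CLN2,-2.30102999566398
p0_CLN2,-2.30102999566398
m0_CLB5,-2.30102999566398
p0_CLB5,-2.30102999566398
m0_CLB2,-2.30102999566398
p0_CLB2,-2.30102999566398
m0_SWI4,-2.30102999566398
p0_SWI4,-2.30102999566398
m0_NDD1,-2.30102999566398
p0_NDD1,-2.30102999566398
m0_SWI5,-2.30102999566398
p0_SWI5,-2.30102999566398
m0_HCM1,-2.30102999566398
p0_HCM1,-2.30102999566398
m0_YOX1,-2.30102999566398
p0_YOX1,-2.30102999566398
sigma_tc,-0.698970004336019
sigma_ss,-0.698970004336019
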