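# GEMM exposure-response constants, adults age > 25, single aggregate stratum
# per cause. Transcribed from the GEMM source publication's supplementary
# tables (fits including the Chinese cohort). theta per log-unit of
# (z/alpha + 1); se_theta same units; alpha, mu, nu in ug/m3.
cause,theta,se_theta,alpha,mu,nu
NCD_LRI,0.1430,0.01807,1.6,15.5,36.8
IHD,0.2969,0.01787,1.9,12.0,40.2
Stroke,0.2720,0.07697,6.2,16.7,23.7
COPD,0.2510,0.06762,6.5,2.5,32.0
LC,0.2942,0.06147,6.2,9.3,29.8
LRI,0.4468,0.11735,6.4,5.7,8.4
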