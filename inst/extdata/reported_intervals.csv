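model,cluster,n_subjects,picp_pct,mpiw,nmpiw
generalized,NA,87,50,0.96,0.24
generalized,NA,87,75,2.28,0.57
generalized,NA,87,85,2.52,0.63
generalized,NA,87,95,3.14,0.79
personalized,NA,87,50,1.63,0.41
personalized,NA,87,75,2.44,0.61
personalized,NA,87,85,2.89,0.72
personalized,NA,87,95,3.12,0.78
hybrid,1,27,50,0.37,0.09
hybrid,1,27,75,1.47,0.37
hybrid,1,27,85,1.85,0.46
hybrid,1,27,95,2.50,0.63
hybrid,2,24,50,0.42,0.11
hybrid,2,24,75,1.38,0.35
hybrid,2,24,85,1.89,0.47
hybrid,2,24,95,2.38,0.60
hybrid,3,20,50,0.59,0.15
hybrid,3,20,75,1.77,0.44
hybrid,3,20,85,1.69,0.42
hybrid,3,20,95,2.81,0.70
hybrid,4,16,50,0.42,0.11
hybrid,4,16,75,1.48,0.37
hybrid,4,16,85,2.04,0.51
hybrid,4,16,95,2.67,0.67
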