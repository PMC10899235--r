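cycle_id,predicted_fold,predicted_dir,omega,ddg,ddg_sd
aE45A+aP272G,7.69,loss,0.77,-0.64,0.24
aV46A+aI264A,34.7,loss,0.44,-2.04,0.82
aV46A+aP265A,2.56,loss,1.34,0.72,0.33
aV46A+aP265G,24.2,loss,0.15,-4.69,1.90
aV46A+aP272G,33.0,loss,0.46,-1.94,0.79
aI264A+aP265G,6.38,loss,0.11,-5.50,2.48
aI264A+aP272G,8.72,loss,0.66,-1.01,0.39
aE45A+aV46A,30.6,loss,,,
aE45A+aV46A+aP272G,88.1,loss,,,
aV46A+aI264A+aP265G,73.1,loss,0.01,-11.1,5.7
aV46A+aI264A+aP272G,99.9,loss,0.11,-5.43,2.51
aS266A+gG182A/dG188A,22.6,loss,0.22,-3.77,1.57
aS266A+gE183A/dE189A,8.11,loss,0.38,-2.42,1.05
aT267A+gG182A/dG188A,14.9,loss,0.24,-3.56,1.40
aT267A+gF221A/dF227A,3.29,loss,,,
aS268A+gG182A/dG188A,1.20,loss,0.98,-0.05,0.02
aS268A+gK218A/dK224A,37.3,gain,1.93,1.62,0.88
aS269A+gG182A/dG188A,2.08,loss,,,
aS269A+gK218A/dK224A,21.5,gain,1.00,0.00,0.00
aS269A+gL220A/dL226A,5.49,gain,,,
aS266A/aT267A+gG182A/dG188A,65.7,loss,0.05,-7.37,3.49
aS266A/aT267A+gE183A/dE189A,23.6,loss,0.12,-5.20,2.95
aS268A/aS269A+gG182A/dG188A,2.05,gain,1.10,0.24,0.11
aS268A/aS269A+gK218A/dK224A,91.5,gain,1.71,1.33,0.96
aSTSS-GGGG+gG182A,3.80,loss,0.58,-1.36,0.66
aSTSS-GGGG+dG188A,3.12,loss,0.75,-0.70,0.23
aSTSS-GGGG+gG182A/dG188A,7.77,loss,0.41,-2.20,0.95
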