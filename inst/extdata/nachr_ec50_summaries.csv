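construct,ec50_mean,ec50_sd,hill_mean,hill_sd,n,status
WT,9.40,1.82,1.78,0.35,87,functional
aE45R,0.600,0.316,1.39,0.21,8,functional
aE45A,25.1,5.5,1.83,0.31,8,functional
aE45K,,,,,,NR
aV46A,108,21,2.00,0.41,8,functional
aR209Q,,,,,,NE
aR209E,,,,,,NE
aI264A,28.5,6.3,1.45,0.19,10,functional
aP265A,2.10,0.65,1.58,0.35,9,functional
aP265G,19.8,5.5,1.85,0.54,8,functional
aP272G,27.1,4.9,1.63,0.15,10,functional
aS266A,41.6,7.3,1.58,0.20,8,functional
aT267A,27.4,3.1,1.57,0.17,8,functional
aS268A,2.21,0.33,1.77,0.28,8,functional
aS269A,3.83,0.30,1.97,0.47,8,functional
aS266A+aT267A+aS268A+aS269A,4.32,1.42,2.12,0.26,8,functional
aSTSS-GGGG,14.3,2.2,1.79,0.13,8,functional
bETSL-GGGG,14.0,1.5,1.85,0.18,14,functional
dETAL-GGGG,21.5,3.2,1.63,0.15,7,functional
gETSL-GGGG,19.7,2.6,1.51,0.18,8,functional
abdg-STSS-GGGG,16.2,3.4,2.14,0.47,7,functional
gG182A,23.4,2.8,1.53,0.26,8,functional
dG188A,19.3,3.5,1.59,0.20,8,functional
gG182A+dG188A,31.0,2.1,1.68,0.30,9,functional
gE183A,15.9,3.3,1.69,0.15,8,functional
dE189A,10.2,1.1,1.80,0.21,8,functional
gE183A+dE189A,16.3,4.0,1.50,0.51,8,functional
gK218A,2.39,0.66,1.91,0.25,8,functional
dK224A,4.24,0.98,1.84,0.26,9,functional
gK218A+dK224A,0.956,0.434,2.14,0.57,9,functional
gP219A,11.8,1.5,2.07,0.56,8,functional
dP225A,12.0,1.5,1.93,0.59,8,functional
gP219A+dP225A,12.0,1.4,1.67,0.59,8,functional
gL220A,8.83,2.14,1.81,0.11,8,functional
dL226A,4.48,0.70,2.20,0.35,8,functional
gL220A+dL226A,6.42,0.81,1.87,0.33,8,functional
gF221A,17.6,3.0,1.72,0.28,8,functional
dF227A,5.67,0.78,2.10,0.71,8,functional
gF221A+dF227A,18.0,7.2,2.04,0.25,8,functional
aE45R+aR209Q,9.16,2.47,1.92,0.40,8,functional
aE45R+aR209E,9.80,2.23,1.72,0.09,8,functional
aE45A+aV46A,,,,,,NR
aE45A+aP272G,55.8,8.2,1.49,0.18,8,functional
aV46A+aI264A,143,27,1.69,0.28,8,functional
aV46A+aP265A,32.2,6.0,2.01,0.26,8,functional
aV46A+aP265G,34.2,3.6,1.99,0.22,7,functional
aV46A+aP272G,142,33,2.29,0.50,8,functional
aI264A+aP265G,6.52,1.32,1.42,0.33,8,functional
aI264A+aP272G,54.5,9.8,1.59,0.38,9,functional
aE45A+aV46A+aP272G,,,,,,NR
aV46A+aI264A+aP265G,7.80,1.20,1.66,0.26,8,functional
aV46A+aI264A+aP272G,105,14,2.11,0.52,8,functional
aS266A+gG182A/dG188A,46.3,6.7,2.15,0.23,8,functional
aS266A+gE183A/dE189A,28.7,4.8,1.87,0.37,8,functional
aT267A+gG182A/dG188A,33.2,3.5,2.25,0.54,8,functional
aT267A+gF221A/dF227A,,,,,,NR
aS268A+gG182A/dG188A,11.0,3.1,1.82,0.49,8,functional
aS268A+gK218A/dK224A,0.486,0.126,2.22,0.45,8,functional
aS269A+gG182A/dG188A,,,,,,NR
aS269A+gK218A/dK224A,0.439,0.126,2.03,0.73,4,functional
aS269A+gL220A/dL226A,,,,,,NR
aS266A/aT267A+gG182A/dG188A,31.5,4.6,2.13,0.32,9,functional
aS266A/aT267A+gE183A/dE189A,27.3,9.2,2.30,0.69,8,functional
aS268A/aS269A+gG182A/dG188A,5.05,0.97,1.96,0.72,8,functional
aS268A/aS269A+gK218A/dK224A,0.176,0.064,2.99,0.92,5,functional
aSTSS-GGGG+gG182A,20.6,8.2,1.65,0.22,8,functional
aSTSS-GGGG+dG188A,22.1,2.4,1.87,0.21,8,functional
aSTSS-GGGG+gG182A/dG188A,30.1,5.9,1.81,0.54,8,functional
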