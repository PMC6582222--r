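phase,process,label,dG_act,dG_rxn,K_printed,k_printed,tau_printed,K_ok,k_ok,tau_ok
gas,deamination,1A-step,61.11,21.72,2.82e-16,9.37e-33,1.26e+16,FALSE,TRUE,TRUE
gas,deamination,2A-step,47.72,-27.48,1.43e+20,1.44e-22,2.3e+42,TRUE,FALSE,TRUE
gas,deamination,A-process,71.05,-5.76,16800,4.8e-40,2.3e+42,TRUE,TRUE,FALSE
gas,deamination,1B-step,59.6,9.5,1.08e-07,2.79e-31,7.7e+23,TRUE,FALSE,TRUE
gas,deamination,2B-step,54.45,-8.27,1160000,6.07e-28,8.76e+33,TRUE,FALSE,FALSE
gas,deamination,B-process,63.95,0.67,0.678,7.74e-35,8.76e+33,FALSE,TRUE,FALSE
gas,oxidation,3C-step,53.9,4.61,0.000416,1.82e-27,2.28e+33,TRUE,TRUE,FALSE
gas,oxidation,4C-step,75.3,-2.79,111,3.76e-43,3.03e+44,TRUE,TRUE,TRUE
gas,oxidation,C-process,79.91,1.82,0.0463,1.52e-46,3.03e+44,TRUE,TRUE,TRUE
gas,amination,5D-step,42.51,-1.69,17.4,4.11e-19,4.22e+19,TRUE,TRUE,TRUE
gas,amination,6D-step,53.46,18.67,2.03e-14,3.83e-27,5.29e+12,TRUE,TRUE,TRUE
gas,amination,D-process,51.77,16.98,3.52e-13,6.66e-26,5.29e+12,TRUE,TRUE,TRUE
gas,amination,5E-step,54.69,4.54,0.000468,4.79e-28,9.6e+23,TRUE,TRUE,TRUE
gas,amination,6E-step,52.52,3.87,0.00145,8.76e-30,7.75e+22,TRUE,FALSE,TRUE
gas,amination,E-process,57.06,8.41,6.79e-07,8.76e-30,7.75e+22,TRUE,TRUE,TRUE
gas,global,global,74.15,4.07,0.00103,2.56e-42,4.05e+38,TRUE,TRUE,TRUE
solution,deamination,1A-step,59.31,17.31,2.01e-13,1.96e-31,1.03e+18,TRUE,TRUE,TRUE
solution,deamination,2A-step,50.74,-26.86,5.02e+19,3.78e-25,1.35e+44,TRUE,TRUE,TRUE
solution,deamination,A-process,68.05,-9.63,11600000,7.62e-38,1.35e+44,TRUE,TRUE,TRUE
solution,deamination,1B-step,55.25,4.9,0.000255,1.86e-28,1.37e+24,TRUE,TRUE,TRUE
solution,deamination,2B-step,55.3,-10.68,68100000,1.71e-28,3.98e+35,TRUE,TRUE,TRUE
solution,deamination,B-process,60.3,-5.78,17400,3.68e-32,3.98e+35,TRUE,TRUE,TRUE
solution,oxidation,3C-step,56.3,3.1,0.00532,3.16e-29,1.68e+26,TRUE,TRUE,TRUE
solution,oxidation,4C-step,79.41,8.85,3.23e-07,3.55e-46,9.1e+38,TRUE,TRUE,TRUE
solution,oxidation,C-process,82.51,11.95,1.72e-09,1.89e-48,9.1e+38,TRUE,TRUE,TRUE
solution,amination,5D-step,48.61,7.73,2.14e-06,1.38e-23,1.55e+17,TRUE,TRUE,TRUE
solution,amination,6D-step,54.09,29.43,2.6e-22,1.32e-27,187000,TRUE,TRUE,TRUE
solution,amination,D-process,61.82,37.16,5.56e-28,2.82e-33,187000,TRUE,TRUE,TRUE
solution,amination,5E-step,57.88,8.81,3.45e-07,2.19e-30,1.58e+23,TRUE,TRUE,TRUE
solution,amination,6E-step,59.54,15.78,9.1e-14,1.33e-31,6.85e+17,FALSE,TRUE,FALSE
solution,amination,E-process,68.35,24.59,9.21e-19,2.13e-34,6.85e+17,TRUE,FALSE,FALSE
solution,global,global,72.88,26.9,1.86e-20,2.18e-41,8.53e+20,TRUE,TRUE,TRUE
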