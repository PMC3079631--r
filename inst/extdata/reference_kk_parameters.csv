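construct,protocol,Lp_um_min_atm,Ps_1e3_cm_min,sigma_assumed
Water,sucrose_2min,1.40,0,1
DrAqp3b-WT,sucrose_2min,2.15,0,1
DrAqp3b-H53A/G54H/T85A,sucrose_2min,1.94,0,1
DrAqp3b-T85A,sucrose_2min,2.57,0,1
HsAQP3,sucrose_2min,1.93,0,1
Water,sucrose_10min,0.69,0,1
DrAqp3b-WT,sucrose_10min,0.89,0,1
DrAqp3b-H53A/G54H/T85A,sucrose_10min,0.88,0,1
DrAqp3b-T85A,sucrose_10min,1.02,0,1
HsAQP3,sucrose_10min,0.87,0,1
Water,eg_1.3M,0.36,0.47,0.9
DrAqp3b-WT (1 ng),eg_1.3M,2.15,17.59,0.8
DrAqp3b-H53A/G54H/T85A (1 ng),eg_1.3M,1.55,13.06,0.8
DrAqp3b-T85A (1 ng),eg_1.3M,2.64,25.49,0.8
HsAQP3 (1 ng),eg_1.3M,1.31,10.73,0.8
DrAqp3b-WT (20 ng),eg_1.3M,2.63,40.06,0.8
DrAqp3b-H53A/G54H/T85A (20 ng),eg_1.3M,2.27,36.58,0.8
DrAqp3b-T85A (20 ng),eg_1.3M,3.24,53.91,0.8
HsAQP3 (20 ng),eg_1.3M,1.96,22.24,0.8
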