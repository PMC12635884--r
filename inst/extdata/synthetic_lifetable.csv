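# Synthetic abridged life table and baseline lung-cancer mortality rates.
# NOT observed data: Gompertz-Makeham survival and an exponential-with-
# plateau lung-cancer mortality curve, shaped to resemble a contemporary
# US population. surv_* is survival from birth to the exact age;
# lung_mort_* is the annual baseline lung-cancer mortality hazard.
age,surv_male,surv_female,lung_mort_male,lung_mort_female
0,1,1,0,0
5,0.997811,0.998398,0,0
10,0.995512,0.996734,0,0
15,0.993036,0.994966,0,0
20,0.990275,0.993029,0,0
25,0.987057,0.990814,0,0
30,0.983109,0.988146,0,0
35,0.977998,0.98474,0,0
40,0.97104,0.980135,1e-04,7e-05
45,0.961162,0.973587,0.000169046,0.000118332
50,0.946703,0.963906,0.000285765,0.000200036
55,0.925127,0.94921,0.000483074,0.000338152
60,0.892696,0.92658,0.000816617,0.000571632
65,0.844166,0.89164,0.00138046,0.00096632
70,0.772873,0.838208,0.00233361,0.00163352
75,0.671921,0.758502,0.00394487,0.00276141
80,0.537744,0.644962,0.00666863,0.00466804
85,0.376972,0.495443,0.00666863,0.00466804
90,0.213799,0.322433,0.00666863,0.00466804
95,0.0863855,0.16008,0.00666863,0.00466804
100,0.020289,0.0510923,0.00666863,0.00466804
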