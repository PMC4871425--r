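# synthetic-dm20 (compact phase-1 mixture)
# synthetic stand-in mixture; one line per component: rho alpha_A..alpha_Y (ACDEFGHIKLMNPQRSTVWY)
20
0.078050 1.262440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.019250 0.062440 1.215400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.053640 0.062440 0.015400 1.242912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.062950 0.062440 0.015400 0.042912 1.250360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.038560 0.062440 0.015400 0.042912 0.050360 1.230848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.073770 0.062440 0.015400 0.042912 0.050360 0.030848 1.259016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.021990 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 1.217592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.051420 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 1.241136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.057440 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 1.245952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.090190 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 1.272152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.022430 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 1.217944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.044870 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 1.235896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.052030 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 1.241624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.042640 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 1.234112 0.041032 0.056960 0.046728 0.051528 0.010640 0.025728
0.051290 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 1.241032 0.056960 0.046728 0.051528 0.010640 0.025728
0.071200 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 1.256960 0.046728 0.051528 0.010640 0.025728
0.058410 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 1.246728 0.051528 0.010640 0.025728
0.064410 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 1.251528 0.010640 0.025728
0.013300 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 1.210640 0.025728
0.032160 0.062440 0.015400 0.042912 0.050360 0.030848 0.059016 0.017592 0.041136 0.045952 0.072152 0.017944 0.035896 0.041624 0.034112 0.041032 0.056960 0.046728 0.051528 0.010640 1.225728
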