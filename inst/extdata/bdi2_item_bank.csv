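"item","label","a","b1","b2","b3","se_a","se_b1","se_b2","se_b3"
1,"Sadness",2.38,1.1,2.75,3.13,0.06,0.05,0.12,0.15
2,"Pessimism",2.2,1.12,2.57,3.35,0.05,0.05,0.09,0.16
3,"Past failure",2.04,1.32,1.98,3.41,0.05,0.05,0.07,0.14
4,"Loss of pleasure",2.27,0.95,2.34,3.25,0.05,0.05,0.08,0.15
5,"Guilty feelings",1.72,0.75,2.96,3.78,0.04,0.03,0.08,0.13
6,"Punishment feelings",1.74,1.46,2.39,2.63,0.05,0.05,0.07,0.07
7,"Self-dislike",2.86,1.24,1.6,2.54,0.07,0.07,0.09,0.14
8,"Self-criticalness",1.62,0.25,1.78,3.24,0.03,0.03,0.04,0.08
9,"Suicidal thoughts",2.12,1.89,3.22,3.6,0.07,0.08,0.15,0.19
10,"Crying",1.52,1.16,1.93,2.73,0.04,0.03,0.04,0.06
11,"Agitation",1.59,0.83,2.9,3.19,0.04,0.03,0.06,0.08
12,"Loss of interest",2.73,0.89,2.26,2.87,0.06,0.05,0.11,0.15
13,"Indecisiveness",2.03,0.78,1.88,2.12,0.04,0.04,0.06,0.06
14,"Worthlessness",3.31,1.31,1.8,2.72,0.09,0.1,0.12,0.2
15,"Loss of energy",2.35,0.4,1.96,3.05,0.05,0.04,0.07,0.13
16,"Changes in sleep",1.58,0.03,1.69,3.04,0.03,0.03,0.04,0.07
17,"Irritability",2.13,0.65,2.1,2.93,0.04,0.04,0.07,0.11
18,"Changes in appetite",1.4,0.48,2.31,3.28,0.03,0.03,0.04,0.07
19,"Concentration difficulty",2.07,0.57,1.6,2.84,0.04,0.03,0.05,0.09
20,"Tiredness or fatigue",2.24,0.32,1.75,2.52,0.04,0.03,0.06,0.09
21,"Loss of interest in sex",1.32,1.91,3.26,4.44,0.04,0.04,0.07,0.12
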