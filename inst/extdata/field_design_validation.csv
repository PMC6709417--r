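no,design,family,sens_best,sens_eval,diff_sensitivity,spec_best,spec_eval,diff_specificity
1,7+13,A,0.98,0.98,0.00,0.96,0.94,-0.02
2,7+14,A,0.98,0.96,-0.02,0.97,0.94,-0.03
3,8+13,A,0.99,0.98,-0.01,0.96,0.93,-0.03
4,8+14,A,0.99,0.97,-0.02,0.96,0.92,-0.04
5,9+13,A,0.99,0.98,-0.01,0.95,0.93,-0.02
6,9+14,A,0.99,0.98,-0.01,0.96,0.89,-0.07
7,2+7+13,A,0.98,0.99,0.01,0.94,0.88,-0.06
8,2+7+14,A,1.00,0.99,-0.01,0.94,0.89,-0.05
9,2+8+13,A,0.97,1.00,0.03,0.93,0.87,-0.06
10,2+8+14,A,0.99,1.00,0.01,0.93,0.89,-0.04
11,2+9+13,A,0.97,1.00,0.03,0.92,0.85,-0.07
12,2+9+14,A,0.99,1.00,0.01,0.92,0.87,-0.05
13,3+7+13,A,0.99,0.99,0.00,0.94,0.91,-0.03
14,3+7+14,A,1.00,1.00,0.00,0.93,0.86,-0.07
15,3+8+13,A,0.99,1.00,0.01,0.94,0.89,-0.05
16,3+8+14,A,1.00,1.00,0.00,0.93,0.85,-0.08
17,3+9+13,A,0.99,1.00,0.01,0.95,0.89,-0.06
18,3+9+14,A,0.99,1.00,0.01,0.93,0.86,-0.07
19,5+7,B,0.98,0.99,0.01,0.94,0.89,-0.05
20,5+8,B,0.99,0.99,0.00,0.94,0.89,-0.05
21,5+9,B,0.98,0.99,0.01,0.95,0.89,-0.06
22,1+5+7,B,0.89,0.89,0.00,0.93,0.90,-0.03
23,1+5+8,B,0.91,0.95,0.04,0.94,0.90,-0.04
24,1+5+9,B,0.96,0.99,0.03,0.95,0.92,-0.03
25,2+5+7,B,0.93,1.00,0.07,0.94,0.89,-0.05
26,2+5+8,B,0.95,1.00,0.05,0.95,0.88,-0.07
27,2+5+9,B,0.97,1.00,0.03,0.95,0.87,-0.08
28,3+5+7,B,0.97,0.99,0.02,0.97,0.91,-0.06
29,3+5+8,B,0.99,0.99,0.00,0.97,0.92,-0.05
30,3+5+9,B,0.99,1.00,0.01,0.97,0.92,-0.05
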