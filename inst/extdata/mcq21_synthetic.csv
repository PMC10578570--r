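item_id,set_label,immediate_amount,delayed_amount,delay_days,k_nominal
1,small,24,35,13,0.035
2,medium,52,58,60,0.0019
3,large,83,85,35,0.0007
4,small,25,30,40,0.005
5,medium,20,55,7,0.25
6,large,66,80,16,0.013
7,small,34,35,43,0.0007
8,medium,40,55,11,0.035
9,large,33,80,15,0.094
10,small,15,35,14,0.094
11,medium,50,60,40,0.005
12,large,76,85,62,0.0019
13,small,11,30,7,0.25
14,medium,53,55,55,0.0007
15,large,55,75,10,0.035
16,small,27,30,59,0.0019
17,medium,25,60,15,0.094
18,large,31,85,7,0.25
19,small,28,35,19,0.013
20,medium,47,58,18,0.013
21,large,68,82,41,0.005
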