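"reach_id","row","col"
1,27,26
1,27,25
1,26,24
1,26,23
2,26,23
2,26,22
2,25,21
2,25,20
3,25,20
3,25,19
3,24,18
3,24,17
4,24,17
4,24,16
4,23,15
4,23,14
5,23,14
5,23,13
5,22,12
5,22,11
6,22,11
6,22,10
6,21,9
6,21,8
7,21,8
7,21,7
7,20,6
7,20,5
8,20,5
8,20,4
8,19,3
8,19,2
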