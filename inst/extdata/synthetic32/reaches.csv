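"reach_id","from_node","to_node","length_km","discharge_m3s"
1,1,2,3.16227766016838,778.210041118076
2,2,3,3.16227766016838,70.4512337417194
3,3,4,3.16227766016838,2.31371486780524
4,4,5,3.16227766016838,597.162790883331
5,5,6,3.16227766016838,2.3648540630754
6,6,7,3.16227766016838,46.5841960076642
7,7,8,3.16227766016838,3.47309233168612
8,8,9,3.16227766016838,922.289297592774
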