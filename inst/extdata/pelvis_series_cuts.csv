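plane_label,patient,desired_margin_mm,sm_mm,l_mm
1,2,6,5.2,2.1
2,4,15,14.2,2.5
3,5,10,6.6,4.4
4,7,10,10.3,1.1
5,9,3,2.8,2.8
6,10,12,12.1,2.7
7,10,10,8.0,1.5
8,11,5,3.5,2.7
9,11,5,5.7,2.6
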