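"task","age_lo","age_hi","mean","sd"
"counting",8,9,21.25,6
"counting",9,10,23.75,6
"counting",10,11,26.25,6
"counting",11,12,28.75,6
"counting",12,13,31.25,6
"counting",13,14,33.75,6
"counting",14,15,36.25,6
"counting",15,16,38.75,6
"reading",8,9,25.5,8
"reading",9,10,28.5,8
"reading",10,11,31.5,8
"reading",11,12,34.5,8
"reading",12,13,37.5,8
"reading",13,14,40.5,8
"reading",14,15,43.5,8
"reading",15,16,46.5,8
"writing",8,9,19,5
"writing",9,10,21,5
"writing",10,11,23,5
"writing",11,12,25,5
"writing",12,13,27,5
"writing",13,14,29,5
"writing",14,15,31,5
"writing",15,16,33,5
"multiplications",8,9,8.5,3.5
"multiplications",9,10,9.5,3.5
"multiplications",10,11,10.5,3.5
"multiplications",11,12,11.5,3.5
"multiplications",12,13,12.5,3.5
"multiplications",13,14,13.5,3.5
"multiplications",14,15,14.5,3.5
"multiplications",15,16,15.5,3.5
"addition_subtraction",8,9,7.6,3
"addition_subtraction",9,10,8.8,3
"addition_subtraction",10,11,10,3
"addition_subtraction",11,12,11.2,3
"addition_subtraction",12,13,12.4,3
"addition_subtraction",13,14,13.6,3
"addition_subtraction",14,15,14.8,3
"addition_subtraction",15,16,16,3
"choose_largest",8,9,9.4,2.5
"choose_largest",9,10,10.2,2.5
"choose_largest",10,11,11,2.5
"choose_largest",11,12,11.8,2.5
"choose_largest",12,13,12.6,2.5
"choose_largest",13,14,13.4,2.5
"choose_largest",14,15,14.2,2.5
"choose_largest",15,16,15,2.5
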