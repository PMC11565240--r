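variable,level,normal,stunted,overweight,cso
total,total,1331,448,4,4
sex,male,699,263,3,2
sex,female,632,185,1,2
wealth_q,Q1,290,164,0,2
wealth_q,Q2,332,116,1,1
wealth_q,Q3,347,101,2,0
wealth_q,Q4,362,67,1,1
residence,urban,363,70,2,1
residence,rural,968,378,2,3
hh_size,le5,817,265,3,4
hh_size,gt5,514,183,1,0
mat_edu,le6y,969,372,2,3
mat_edu,gt6y,359,74,2,0
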