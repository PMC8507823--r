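week,label
7,US declares public health emergency
10,Cruise ship passengers test positive
11,WHO pandemic declaration; US national emergency
18,Antiviral emergency use authorization
19,At-home saliva test authorized
24,US reaches 2 million cases
27,Projection of 100000 cases per day
29,Promising vaccine results reported
30,Further vaccine and treatment news
44,CMS coverage rules; European lockdowns
45,US election day
51,Election result confirmed
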