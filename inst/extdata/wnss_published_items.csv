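item,discrimination,information,in_short_form,in_nss_sf
1,0.235,1.06,FALSE,FALSE
2,0.329,1.55,FALSE,FALSE
3,0.227,0.97,FALSE,FALSE
4,0.348,1.63,FALSE,FALSE
5,0.655,3.26,FALSE,FALSE
6,0.832,4.15,TRUE,FALSE
7,1.090,5.45,TRUE,TRUE
8,0.214,0.84,FALSE,TRUE
9,0.458,2.23,FALSE,FALSE
10,1.688,8.44,TRUE,FALSE
11,0.605,3.00,TRUE,FALSE
12,0.123,0.38,FALSE,FALSE
13,0.671,3.33,TRUE,FALSE
14,0.298,1.33,FALSE,FALSE
15,0.148,0.54,FALSE,FALSE
16,0.345,1.62,FALSE,FALSE
17,0.539,2.64,FALSE,FALSE
18,1.206,6.03,TRUE,TRUE
19,1.214,6.07,TRUE,TRUE
20,0.229,0.96,FALSE,FALSE
21,0.775,3.86,TRUE,TRUE
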