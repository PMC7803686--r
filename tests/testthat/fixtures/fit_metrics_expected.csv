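case,r_squared,rmse,aad_percent
1,0.934131153261,0.604109663780,6.308887996111
2,0.904931820153,0.786651322291,6.337286694266
3,0.979191895718,0.216422320622,4.518101480378
4,0.940770279414,0.582524264574,7.963656103635
5,0.977842026213,0.312994134784,4.712817580468
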