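case,observed,predicted
1,7.965604,7.952221
1,4.949906,4.527657
1,8.727381,9.494865
1,7.276312,7.842258
1,1.847596,1.859796
1,9.780601,10.883111
1,7.850257,8.217264
1,8.074579,7.380737
2,5.991263,5.734641
2,1.574355,1.518917
2,8.448681,8.898412
2,6.684980,6.929279
2,7.822790,8.145662
2,4.190734,4.371280
2,9.736282,11.821450
2,9.038090,8.670768
3,3.932428,4.224707
3,4.334137,4.569548
3,5.226002,4.878206
3,2.705242,2.768047
3,2.169294,2.194607
3,5.281344,5.396841
3,3.042184,3.307289
3,7.028326,7.185476
4,2.799174,2.722157
4,1.066260,1.225660
4,8.082319,7.382527
4,6.983658,7.659870
4,7.346488,6.110170
4,8.026561,7.757763
4,5.130242,5.213738
4,6.118671,6.477361
5,6.032864,5.478171
5,3.735551,3.921268
5,1.277361,1.295554
5,4.930457,5.270898
5,2.931262,2.806023
5,4.676758,4.750903
5,8.680628,9.223680
5,3.105455,3.009389
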