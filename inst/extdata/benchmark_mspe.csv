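rule,nhanes,abalone,boston,ozone,servo
parent,0.1395,4.5088,32.2552,15.6340,0.2729
leaf,0.1398,4.5119,30.9823,15.8862,0.2774
variance,0.1398,4.5475,33.7808,15.9173,0.2601
range,0.1398,4.5475,32.6826,15.8043,0.2676
icr10,0.1399,4.5497,33.7754,15.8223,0.2241
icr25,0.1397,4.5398,32.4181,15.9343,0.2235
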