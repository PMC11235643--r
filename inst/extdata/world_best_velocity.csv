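boat_class,sex,velocity_ms
1X,M,5.118
1X,F,4.675
2-,M,5.427
2-,F,4.908
2X,M,5.560
2X,F,5.033
4-,M,5.920
4-,F,5.342
4X,M,6.020
4X,F,5.452
8+,M,6.276
8+,F,5.666
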