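fold	auc
1	0.881
2	0.91
3	0.894
4	0.886
5	0.878
6	0.872
7	0.896
8	0.892
9	0.902
10	0.909
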