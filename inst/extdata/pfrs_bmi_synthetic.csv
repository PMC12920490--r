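silhouette,bmi
1,12.5
2,15.0
3,17.5
4,20.0
5,22.5
6,25.0
7,27.5
8,30.0
9,35.0
10,41.5
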