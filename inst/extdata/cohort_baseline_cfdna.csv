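patient,histology,study_part,baseline_ng_per_ml
1,AC,1,5.85
2,SCC,1,17.78
3,SCC,1,1.50
4,SCC,1,4.13
5,AC,2,3.60
6,AC,2,2.79
7,SCC,2,7.85
8,SCC,2,8.27
9,AC,2,2.52
10,SCC,2,1.47
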