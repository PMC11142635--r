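"region_id","region"
1,"L-fronto-orbital"
2,"L-frontal-basal"
3,"L-frontal-parasagittal"
4,"L-frontal-periventricular"
5,"L-frontal-lateral"
6,"L-frontal-operculum"
7,"L-hippocampus"
8,"L-amygdala"
9,"L-uncus"
10,"L-temporal-anterior-neocortical"
11,"L-temporal-posterior-neocortical"
12,"L-gyrus-parahippocampalis"
13,"L-insula-anterior"
14,"L-insula-posterior"
15,"L-central"
16,"L-parietal"
17,"L-occipital"
18,"R-fronto-orbital"
19,"R-frontal-basal"
20,"R-frontal-parasagittal"
21,"R-frontal-periventricular"
22,"R-frontal-lateral"
23,"R-frontal-operculum"
24,"R-hippocampus"
25,"R-amygdala"
26,"R-uncus"
27,"R-temporal-anterior-neocortical"
28,"R-temporal-posterior-neocortical"
29,"R-gyrus-parahippocampalis"
30,"R-insula-anterior"
31,"R-insula-posterior"
32,"R-central"
33,"R-parietal"
34,"R-occipital"
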