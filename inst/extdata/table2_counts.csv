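subtype,lineage,HS,D4,RAP,CCI
B naive,B cells,251,8,93,84
B intermediate,B cells,178,7,39,28
B memory,B cells,140,3,55,17
Plasmablast,B cells,73,97,198,179
CD4 T naive,CD4 T,1936,56,21,305
CD4 T proliferating,CD4 T,20,7,13,3
CD4 TEM,CD4 T,157,11,22,33
CD4 TCM,CD4 T,5683,676,1290,1042
CD4 CTL,CD4 T,11,0,3,7
Treg,CD4 T,149,16,24,36
CD8 T naive,CD8 T,401,6,20,118
CD8 T proliferating,CD8 T,10,0,11,8
CD8 TEM,CD8 T,926,80,146,453
CD8 TCM,CD8 T,153,4,14,24
dnT,other T,60,5,21,10
gdT,other T,117,10,12,7
MAIT,other T,64,1,12,21
NK,NK,1815,47,381,595
NK Proliferating,NK,60,5,18,52
NK CD56bright,NK,123,5,22,43
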