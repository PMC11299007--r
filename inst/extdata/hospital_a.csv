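Evidence,Weight,Excellent,Good,Average,Poor,Worst
MF,1,19.75%,37.04%,39.51%,2.47%,1.23%
MS,1,18.52%,39.51%,35.80%,3.70%,2.47%
MP,1,12.35%,33.33%,49.38%,4.94%,0.00%
MO,1,14.81%,48.15%,30.86%,6.17%,0.00%
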