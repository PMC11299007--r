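Evidence,Weight,Excellent,Good,Average,Poor,Worst
MF,1,19.72%,53.52%,23.94%,2.82%,0.00%
MS,1,19.72%,49.30%,28.17%,2.81%,0.00%
MP,1,19.72%,45.07%,35.21%,0.00%,0.00%
MO,1,21.13%,47.89%,28.17%,2.81%,0.00%
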