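Evidence,Weight,Excellent,Good,Average,Poor,Worst
MF,1,23.68%,50.00%,22.37%,2.63%,1.32%
MS,1,26.32%,47.37%,21.05%,5.26%,0.00%
MP,1,19.74%,43.42%,31.58%,3.95%,1.31%
MO,1,27.63%,46.05%,23.68%,1.32%,1.32%
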