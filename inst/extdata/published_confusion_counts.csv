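model,split,obs1_correct,obs1_wrong,obs0_wrong,obs0_correct,sp,sn,ac
MI-Entropy,Train,1092,290,412,4438,79.0,91.5,88.7
MI-Entropy,CV,379,87,119,1492,81.3,92.6,90.1
MI-SpectralMoments,Train,1172,214,224,1051,84.6,82.4,83.5
MI-SpectralMoments,CV,385,77,78,347,83.3,81.6,82.5
TM-SpectralMoments,Train,1533,352,36,1762,81.3,98.0,89.5
TM-SpectralMoments,CV,513,120,14,585,81.0,97.7,89.1
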