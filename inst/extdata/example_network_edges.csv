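hemisphere_i,label_i,hemisphere_j,label_j
R,Precentral Gyrus 02,R,Precentral Gyrus 13
R,Superior Frontal Gyrus 02,R,Postcentral gyrus 05
R,Precentral Gyrus 06,R,Postcentral gyrus 05
R,Postcentral gyrus 02,R,Postcentral gyrus 05
R,Superior Frontal Gyrus 02,R,Postcentral gyrus 15
R,Postcentral gyrus 05,R,Postcentral gyrus 15
R,Precentral Gyrus 02,R,Superior Parietal Lobule 04
R,Postcentral gyrus 04,R,Superior Parietal Lobule 04
R,Precentral Gyrus 02,R,Juxtapositional Lobule Cortex (Supplementary Motor Cortex) 01
R,Precentral Gyrus 04,R,Juxtapositional Lobule Cortex (Supplementary Motor Cortex) 01
R,Precentral Gyrus 07,R,Juxtapositional Lobule Cortex (Supplementary Motor Cortex) 01
R,Postcentral gyrus 02,R,Juxtapositional Lobule Cortex (Supplementary Motor Cortex) 01
R,Postcentral gyrus 02,L,Precentral Gyrus 15
R,Postcentral gyrus 05,L,Precentral Gyrus 15
R,Postcentral gyrus 15,L,Precentral Gyrus 15
R,Postcentral gyrus 05,L,Postcentral gyrus 02
R,Postcentral gyrus 05,L,Postcentral gyrus 05
R,Precentral Gyrus 02,L,Superior Parietal Lobule 08
R,Postcentral gyrus 05,L,Superior Parietal Lobule 09
L,Precentral Gyrus 15,L,Superior Parietal Lobule 09
R,Precentral Gyrus 04,L,Superior Parietal Lobule 14
R,Precentral Gyrus 12,L,Superior Parietal Lobule 14
R,Postcentral gyrus 02,L,Superior Parietal Lobule 14
R,Postcentral gyrus 04,L,Superior Parietal Lobule 14
R,Postcentral gyrus 05,L,Superior Parietal Lobule 14
R,Postcentral gyrus 15,L,Superior Parietal Lobule 14
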