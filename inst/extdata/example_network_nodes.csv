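label,hemisphere,x,y,z
Postcentral gyrus 02,L,-14.58,-39.62,65.78
Postcentral gyrus 05,L,-7.87,-39.27,74.46
Precentral Gyrus 15,L,-5.52,-19.86,71.55
Superior Parietal Lobule 08,L,-27.92,-34.42,53.87
Superior Parietal Lobule 09,L,-15.42,-34.39,75.06
Superior Parietal Lobule 14,L,-17.66,-51.44,65.96
Juxtapositional Lobule Cortex (Supplementary Motor Cortex) 01,R,6.69,-4.86,52.19
Postcentral gyrus 02,R,15.39,-39.74,65.79
Postcentral gyrus 04,R,26.43,-34.79,65.5
Postcentral gyrus 05,R,8.6,-39.46,74.54
Postcentral gyrus 15,R,16.36,-34.54,74.8
Precentral Gyrus 02,R,25.84,-20.87,53.1
Precentral Gyrus 04,R,11.02,-27.78,60.74
Precentral Gyrus 06,R,15,-23.75,73.83
Precentral Gyrus 07,R,5.18,-22.09,53.4
Precentral Gyrus 12,R,25.82,-19.77,65.74
Precentral Gyrus 13,R,36.76,-14.45,62.96
Superior Frontal Gyrus 02,R,19.68,-5.47,68.98
Superior Parietal Lobule 04,R,18.76,-51.26,65.97
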