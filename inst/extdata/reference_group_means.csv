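feature,healthy_mean,healthy_sd,koa_mean,koa_sd,tka_mean,tka_sd
hip_rom,37.30,1.05,33.55,1.25,33.77,1.34
knee_rom,61.45,1.63,50.59,2.61,44.63,2.46
hip_com,15.92,2.49,19.27,1.99,18.95,2.29
knee_com,22.13,1.41,23.85,1.74,24.94,1.46
perimeter_stance,138.32,3.15,125.55,5.39,114.09,4.40
perimeter_swing,34.40,2.65,21.08,2.32,23.45,2.40
perimeter_total,172.73,4.75,146.63,7.24,136.58,5.80
area_stance,550.93,28.23,402.76,38.40,398.02,28.24
area_swing,930.89,44.86,593.51,56.18,629.79,51.59
area_total,1481.91,63.39,996.28,88.71,1023.51,75.90
se_hip,0.24,0.01,0.30,0.01,0.21,0.01
se_knee,0.20,0.01,0.24,0.01,0.15,0.01
se_ankle,0.28,0.06,0.38,0.07,0.30,0.07
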