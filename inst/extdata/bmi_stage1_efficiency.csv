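province,y2017,y2018,y2019,y2020
Beijing,0.816,0.907,1,0.722
Tianjin,0.861,1,1,1
Hebei,0.915,0.936,0.945,0.974
Liaoning,0.795,0.926,0.877,0.745
Shanghai,0.981,1,0.795,0.873
Jiangsu,0.862,0.862,0.933,0.984
Zhejiang,1,0.999,0.865,0.876
Fujian,0.87,0.945,0.963,1
Shandong,1,0.94,0.898,0.944
Guangdong,0.878,0.94,0.811,0.899
Hainan,0.875,0.913,0.927,1
Shanxi,0.851,0.986,1,0.965
Jilin,0.875,0.894,1,0.793
Heilongjiang,0.866,0.846,0.911,0.764
Anhui,0.79,0.981,1,1
Jiangxi,1,1,1,1
Henan,1,1,1,1
Hubei,0.825,0.914,0.939,0.98
Hunan,0.966,0.995,0.998,1
Neimenggu,0.894,1,0.875,0.835
Guangxi,0.623,0.807,0.953,1
Chongqing,0.956,0.878,0.887,0.961
Sichuan,0.823,0.806,0.845,0.935
Guizhou,0.666,0.976,0.828,0.862
Yunnan,0.871,0.885,0.891,0.934
Tibet,1,1,1,1
Shaanxi,0.97,0.996,0.908,0.742
Gansu,1,1,0.927,0.91
Qinghai,1,1,1,1
Ningxia,1,1,1,1
Xinjiang,0.717,0.984,0.971,0.663
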