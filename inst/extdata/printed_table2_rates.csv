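province,stratum,hrp,rp,diff,diff_pct
Guizhou,urban,6.8,6.7,-0.1,-1.5
Guizhou,rural,5.0,6.4,1.4,28.0
Guizhou,all,5.4,6.5,1.1,20.4
Guangxi,urban,8.1,8.0,-0.1,-1.2
Guangxi,rural,5.4,6.2,0.8,14.8
Guangxi,all,6.3,6.8,0.5,7.9
Jiangxi,urban,8.0,8.0,0.0,0.0
Jiangxi,rural,7.3,7.9,0.6,8.2
Jiangxi,all,7.5,8.0,0.5,6.7
Anhui,urban,7.8,7.2,-0.6,-7.7
Anhui,rural,6.6,7.5,0.9,13.6
Anhui,all,7.0,7.4,0.4,5.7
Henan,urban,7.7,7.0,-0.7,-9.1
Henan,rural,5.0,5.7,0.7,14.0
Henan,all,5.6,6.0,0.4,7.1
Jiangsu,urban,14.8,14.0,-0.8,-5.4
Jiangsu,rural,10.7,12.1,1.4,13.1
Jiangsu,all,12.6,13.0,0.4,3.2
Chongqing,urban,10.7,10.4,-0.3,-2.8
Chongqing,rural,5.6,6.8,1.2,21.4
Chongqing,all,9.2,9.6,0.4,4.3
Fujian,urban,12.3,10.5,-1.8,-14.6
Fujian,rural,8.8,10.2,1.4,15.9
Fujian,all,10.0,10.3,0.3,3.0
Qinghai,urban,6.1,5.8,-0.3,-4.9
Qinghai,rural,5.1,5.6,0.5,9.8
Qinghai,all,5.4,5.7,0.3,5.6
Ningxia,urban,8.4,7.9,-0.5,-6.0
Ningxia,rural,5.3,6.1,0.8,15.1
Ningxia,all,6.8,7.0,0.2,2.9
Hebei,urban,9.7,9.4,-0.3,-3.1
Hebei,rural,6.0,6.1,0.1,1.7
Hebei,all,6.9,7.0,0.1,1.4
Jilin,urban,6.8,6.6,-0.2,-2.9
Jilin,rural,4.8,5.0,0.2,4.2
Jilin,all,5.5,5.6,0.1,1.8
Sichuan,urban,9.3,8.5,-0.8,-8.6
Sichuan,rural,5.8,6.2,0.4,6.9
Sichuan,all,7.0,7.1,0.1,1.4
Hainan,urban,9.1,7.6,-1.5,-16.5
Hainan,rural,6.2,7.1,0.9,14.5
Hainan,all,7.3,7.3,0.0,0.0
Hubei,urban,10.2,8.3,-1.9,-18.6
Hubei,rural,4.9,5.4,0.5,10.2
Hubei,all,6.4,6.4,0.0,0.0
Hunan,urban,8.6,7.2,-1.4,-16.3
Hunan,rural,4.9,5.2,0.3,6.1
Hunan,all,5.6,5.6,0.0,0.0
Heilongjiang,urban,8.0,6.7,-1.3,-16.3
Heilongjiang,rural,5.2,5.6,0.4,7.7
Heilongjiang,all,6.2,6.1,-0.1,-1.6
Shandong,urban,8.9,8.3,-0.6,-6.7
Shandong,rural,7.8,8.0,0.2,2.6
Shandong,all,8.2,8.1,-0.1,-1.2
Gansu,urban,7.4,6.5,-0.9,-12.2
Gansu,rural,4.2,4.2,0.0,0.0
Gansu,all,5.2,5.0,-0.2,-3.8
Shanxi,urban,7.8,7.0,-0.8,-10.3
Shanxi,rural,6.2,6.2,0.0,0.0
Shanxi,all,6.7,6.5,-0.2,-3.0
Xizang,urban,4.3,3.3,-1.0,-23.3
Xizang,rural,3.9,4.3,0.4,10.3
Xizang,all,4.1,3.9,-0.2,-4.9
Shaanxi,urban,8.4,7.8,-0.6,-7.1
Shaanxi,rural,6.5,6.5,0.0,0.0
Shaanxi,all,7.3,7.0,-0.3,-4.1
Yunnan,urban,9.3,7.4,-1.9,-20.4
Yunnan,rural,5.8,5.8,0.0,0.0
Yunnan,all,6.4,6.1,-0.3,-4.7
Liaoning,urban,11.9,11.3,-0.6,-5.0
Liaoning,rural,5.9,5.8,-0.1,-1.7
Liaoning,all,8.8,8.4,-0.4,-4.5
Xinjiang,urban,9.7,6.8,-2.9,-29.9
Xinjiang,rural,5.9,5.8,-0.1,-1.7
Xinjiang,all,6.5,6.0,-0.5,-7.7
Inner Mongolia,urban,12.1,8.6,-3.5,-28.9
Inner Mongolia,rural,6.4,6.7,0.3,4.7
Inner Mongolia,all,8.0,7.4,-0.6,-7.5
Guangdong,urban,11.8,8.7,-3.1,-26.3
Guangdong,rural,8.0,10.2,2.2,27.5
Guangdong,all,9.9,9.2,-0.7,-7.1
Zhejiang,urban,21.7,16.0,-5.7,-26.3
Zhejiang,rural,17.9,18.0,0.1,0.6
Zhejiang,all,19.4,17.0,-2.4,-12.4
Tianjin,urban,15.4,11.4,-4.0,-26.0
Tianjin,rural,14.4,10.6,-3.8,-26.4
Tianjin,all,14.9,11.0,-3.9,-26.2
Beijing,urban,34.1,24.2,-9.9,-29.0
Beijing,rural,16.6,10.5,-6.1,-36.7
Beijing,all,27.2,18.1,-9.1,-33.5
Shanghai,urban,23.0,20.8,-2.2,-9.6
Shanghai,rural,30.8,16.5,-14.3,-46.4
Shanghai,all,27.6,17.7,-9.9,-35.9
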