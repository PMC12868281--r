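province,stratum,hrp,rp,diff,diff_pct
Guangdong,urban,2928,3274,346,11.8
Guangdong,rural,1901,2024,123,6.5
Guangdong,all,4829,5298,469,9.7
Jiangsu,urban,2669,2824,155,5.8
Jiangsu,rural,2257,2407,150,6.6
Jiangsu,all,4926,5231,305,6.2
Zhejiang,urban,2202,2314,112,5.1
Zhejiang,rural,2869,2958,89,3.1
Zhejiang,all,5072,5272,200,3.9
Shanghai,urban,687,706,19,2.8
Shanghai,rural,1365,1503,138,10.1
Shanghai,all,2052,2209,157,7.7
Beijing,urban,1422,1488,66,4.6
Beijing,rural,448,513,65,14.5
Beijing,all,1870,2001,131,7.0
Fujian,urban,796,851,55,6.9
Fujian,rural,1143,1202,59,5.2
Fujian,all,1940,2053,113,5.8
Tianjin,urban,414,459,45,10.9
Tianjin,rural,383,426,43,11.2
Tianjin,all,797,884,87,10.9
Xinjiang,urban,183,210,27,14.8
Xinjiang,rural,613,667,54,8.8
Xinjiang,all,796,877,81,10.2
Shanxi,urban,416,443,27,6.5
Shanxi,rural,763,775,12,1.6
Shanxi,all,1179,1219,40,3.4
Hainan,urban,158,170,12,7.6
Hainan,rural,188,195,7,3.7
Hainan,all,347,365,18,5.2
Xizang,urban,17,29,12,70.6
Xizang,rural,50,53,3,6.0
Xizang,all,68,81,13,19.1
Qinghai,urban,58,62,4,6.9
Qinghai,rural,104,109,5,4.8
Qinghai,all,162,172,10,6.2
Ningxia,urban,129,134,5,3.9
Ningxia,rural,102,107,5,4.9
Ningxia,all,232,241,9,3.9
Gansu,urban,311,301,-10,-3.2
Gansu,rural,408,385,-23,-5.6
Gansu,all,718,686,-32,-4.5
Yunnan,urban,369,352,-17,-4.6
Yunnan,rural,1174,1137,-37,-3.2
Yunnan,all,1544,1489,-55,-3.6
Shaanxi,urban,696,669,-27,-3.9
Shaanxi,rural,776,739,-37,-4.8
Shaanxi,all,1472,1408,-64,-4.3
Guizhou,urban,353,335,-18,-5.1
Guizhou,rural,884,835,-49,-5.5
Guizhou,all,1238,1171,-67,-5.4
Jiangxi,urban,578,563,-15,-2.6
Jiangxi,rural,1352,1299,-53,-3.9
Jiangxi,all,1930,1862,-68,-3.5
Guangxi,urban,763,741,-22,-2.9
Guangxi,rural,1059,1007,-52,-4.9
Guangxi,all,1822,1748,-74,-4.1
Jilin,urban,313,294,-19,-6.1
Jilin,rural,412,350,-62,-15.0
Jilin,all,725,644,-81,-11.2
Inner Mongolia,urban,426,393,-33,-7.7
Inner Mongolia,rural,574,525,-49,-8.5
Inner Mongolia,all,1000,917,-83,-8.3
Hebei,urban,931,894,-37,-4.0
Hebei,rural,1712,1662,-50,-2.9
Hebei,all,2643,2556,-87,-3.3
Liaoning,urban,1218,1141,-77,-6.3
Liaoning,rural,648,625,-23,-3.5
Liaoning,all,1866,1765,-101,-5.4
Heilongjiang,urban,547,505,-42,-7.7
Heilongjiang,rural,597,534,-63,-10.6
Heilongjiang,all,1144,1039,-105,-9.2
Chongqing,urban,1318,1254,-64,-4.9
Chongqing,rural,271,230,-41,-15.1
Chongqing,all,1589,1484,-105,-6.6
Hunan,urban,627,595,-32,-5.1
Hunan,rural,1471,1365,-106,-7.2
Hunan,all,2099,1959,-140,-6.7
Hubei,urban,948,893,-55,-5.8
Hubei,rural,1146,1047,-99,-8.6
Hubei,all,2094,1941,-153,-7.3
Anhui,urban,844,803,-41,-4.9
Anhui,rural,1642,1526,-116,-7.1
Anhui,all,2487,2329,-158,-6.4
Sichuan,urban,1450,1373,-77,-5.3
Sichuan,rural,1789,1619,-170,-9.5
Sichuan,all,3239,2992,-247,-7.6
Shandong,urban,1692,1552,-140,-8.3
Shandong,rural,2440,2317,-123,-5.0
Shandong,all,4132,3869,-263,-6.4
Henan,urban,928,883,-45,-4.8
Henan,rural,2229,2001,-228,-10.2
Henan,all,3157,2884,-273,-8.6
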