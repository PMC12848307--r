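"cell_id","vessel_id","timepoint","area_um2","aspect_ratio","width_um","length_um"
"c01","v01","2dpf",467.110901825364,3.37417698402932,11.7659249080422,39.7003130205333
"c02","v02","2dpf",400.19866485454,2.96792138270291,11.6121228380587,34.463867669647
"c03","v03","2dpf",430.983092461684,3.51359213997994,11.075273074003,38.9139924209483
"c04","v01","2dpf",440.369078200813,2.97550376357776,12.1654493832091,36.1983404253536
"c05","v02","2dpf",432.401608597806,3.31894051742231,11.4141589464812,37.8829145997749
"c06","v03","2dpf",415.128654718524,3.58967775381438,10.7538413284785,38.6028249848891
"c01","v01","3dpf",303.33084835328,2.46082444094419,11.1024282214925,27.3211267212772
"c02","v02","3dpf",331.453747355124,3.32298395736145,9.98728272819331,33.1875802834195
"c03","v03","3dpf",335.327314640477,2.91809355788134,10.7197549984836,31.2812480031412
"c04","v01","3dpf",356.577185417762,2.59385459744625,11.724760025302,30.4123226955835
"c05","v02","3dpf",331.309120778519,2.94966329393521,10.5981600568016,31.2610037027979
"c06","v03","3dpf",274.123362466407,3.29511648520141,9.1208988450687,30.0544241442404
"c01","v01","4dpf",301.528806945254,3.10123493614176,9.86045761882023,30.5795956538305
"c02","v02","4dpf",250.412412043,3.16362829770937,8.89682811130829,28.1462571727911
"c03","v03","4dpf",253.900661413606,3.24819264048131,8.8411961744289,28.7179083468315
"c04","v01","4dpf",225.126774684634,2.84848150973077,8.89010463073344,25.3232986602161
"c05","v02","4dpf",268.873477944864,3.1135217589843,9.29283080246976,28.9334309060492
"c06","v03","4dpf",246.256548854428,2.60721032662433,9.71864817684317,25.3385598874943
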