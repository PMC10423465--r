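"drug","year","cost_eur"
"INF",2013,7390
"INF",2014,5027
"INF",2015,4399
"INF",2016,3416
"INF",2017,4191
"INF",2018,3937
"INF",2019,2553
"INF",2020,1466
"INF",2021,1159
"ETN",2013,7121
"ETN",2014,7208
"ETN",2015,7076
"ETN",2016,6576
"ETN",2017,5063
"ETN",2018,3636
"ETN",2019,2611
"ETN",2020,2143
"ETN",2021,1963
"ADA",2013,7556
"ADA",2014,7453
"ADA",2015,7440
"ADA",2016,6324
"ADA",2017,6068
"ADA",2018,6147
"ADA",2019,2008
"ADA",2020,1021
"ADA",2021,746
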