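bird_id,sex,season,total_km,farthest_km,farthest_lat,farthest_lon,period_start,period_end,mass_g,complete
8406,F,2013/14,13670,5199,34.1,-27.8,2014-04-05,2014-04-21,426,TRUE
7360,M,2013/14,8341,2549,56.8,-39.0,2014-04-09,2014-05-02,626,TRUE
7360,M,2014/15,7103,2401,58.4,-37.8,2015-02-16,2015-02-25,626,TRUE
7363,M,2013/14,8504,2443,60.6,-25.6,2014-04-05,2014-04-17,546,TRUE
7363,M,2014/15,7867,2780,56.9,-27.0,2015-04-05,2015-05-03,546,TRUE
7314,F,2014/15,5784,2229,59.6,-39.9,2014-11-14,2014-11-25,542,FALSE
8408,F,2013/14,7670,4473,41.7,-23.8,2014-01-09,2014-01-26,456,FALSE
8408,F,2014/15,10261,4463,38.4,-50.2,2015-04-08,2015-05-13,456,TRUE
8413,M,2014/15,8562,2644,55.6,-41.0,2015-04-14,2015-04-26,602,TRUE
8420,M,2014/15,7490,2914,53.5,-38.6,2015-04-11,2015-04-22,627,TRUE
8422,M,2014/15,7030,2372,58.3,-40.0,2015-04-07,2015-04-17,627,TRUE
8427,M,2014/15,8896,2821,54.7,-36.2,2015-04-05,2015-04-18,562,TRUE
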