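month,sex,mean_km,sd_km,min_km,max_km,n,printed_difference_km
Oct,M,1207,169,908,1459,8,494
Oct,F,1701,1006,998,3194,4,494
Nov,M,1444,178,1160,1654,8,1280
Nov,F,2724,887,1635,3795,4,1280
Dec,M,1595,125,1440,1777,8,1594
Dec,F,3189,987,2085,3987,3,1594
Jan,M,1799,148,1520,1938,8,1952
Jan,F,3885,765,1938,4441,3,1952
Feb,M,2521,570,1617,3005,8,1698
Feb,F,3672,375,3406,3937,2,1698
Apr,M,2890,367,2509,3458,8,1691
Apr,F,4581,109,4509,4653,2,1691
May,M,2798,245,2558,3269,8,1249
May,F,3614,376,3348,3880,2,1249
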