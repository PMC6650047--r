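exercise,predicted,actual,count
SLCMJ,ACL_OP,ACL_OP,1928
SLCMJ,ACL_OP,ACL_NO_OP,526
SLCMJ,ACL_OP,NORM,514
SLCMJ,ACL_NO_OP,ACL_OP,825
SLCMJ,ACL_NO_OP,ACL_NO_OP,1562
SLCMJ,ACL_NO_OP,NORM,525
SLCMJ,NORM,ACL_OP,909
SLCMJ,NORM,ACL_NO_OP,901
SLCMJ,NORM,NORM,1092
DLCMJ,ACL_OP,ACL_OP,2190
DLCMJ,ACL_OP,ACL_NO_OP,339
DLCMJ,ACL_OP,NORM,471
DLCMJ,ACL_NO_OP,ACL_OP,338
DLCMJ,ACL_NO_OP,ACL_NO_OP,2190
DLCMJ,ACL_NO_OP,NORM,472
DLCMJ,NORM,ACL_OP,512
DLCMJ,NORM,ACL_NO_OP,504
DLCMJ,NORM,NORM,1959
SLDJ,ACL_OP,ACL_OP,2012
SLDJ,ACL_OP,ACL_NO_OP,421
SLDJ,ACL_OP,NORM,542
SLDJ,ACL_NO_OP,ACL_OP,604
SLDJ,ACL_NO_OP,ACL_NO_OP,1463
SLDJ,ACL_NO_OP,NORM,908
SLDJ,NORM,ACL_OP,525
SLDJ,NORM,ACL_NO_OP,902
SLDJ,NORM,NORM,1460
DLDJ,ACL_OP,ACL_OP,2501
DLDJ,ACL_OP,ACL_NO_OP,108
DLDJ,ACL_OP,NORM,391
DLDJ,ACL_NO_OP,ACL_OP,109
DLDJ,ACL_NO_OP,ACL_NO_OP,2507
DLDJ,ACL_NO_OP,NORM,384
DLDJ,NORM,ACL_OP,355
DLDJ,NORM,ACL_NO_OP,334
DLDJ,NORM,NORM,2282
SLHop,ACL_OP,ACL_OP,2088
SLHop,ACL_OP,ACL_NO_OP,657
SLHop,ACL_OP,NORM,255
SLHop,ACL_NO_OP,ACL_OP,587
SLHop,ACL_NO_OP,ACL_NO_OP,2129
SLHop,ACL_NO_OP,NORM,284
SLHop,NORM,ACL_OP,267
SLHop,NORM,ACL_NO_OP,291
SLHop,NORM,NORM,2370
HuHo,ACL_OP,ACL_OP,2007
HuHo,ACL_OP,ACL_NO_OP,658
HuHo,ACL_OP,NORM,321
HuHo,ACL_NO_OP,ACL_OP,657
HuHo,ACL_NO_OP,ACL_NO_OP,1803
HuHo,ACL_NO_OP,NORM,523
HuHo,NORM,ACL_OP,175
HuHo,NORM,ACL_NO_OP,389
HuHo,NORM,NORM,2388
CoDP,ACL_OP,ACL_OP,1828
CoDP,ACL_OP,ACL_NO_OP,566
CoDP,ACL_OP,NORM,558
CoDP,ACL_NO_OP,ACL_OP,706
CoDP,ACL_NO_OP,ACL_NO_OP,1640
CoDP,ACL_NO_OP,NORM,552
CoDP,NORM,ACL_OP,364
CoDP,NORM,ACL_NO_OP,485
CoDP,NORM,NORM,2030
CoDU,ACL_OP,ACL_OP,1705
CoDU,ACL_OP,ACL_NO_OP,659
CoDU,ACL_OP,NORM,554
CoDU,ACL_NO_OP,ACL_OP,795
CoDU,ACL_NO_OP,ACL_NO_OP,1326
CoDU,ACL_NO_OP,NORM,717
CoDU,NORM,ACL_OP,567
CoDU,NORM,ACL_NO_OP,784
CoDU,NORM,NORM,1410
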