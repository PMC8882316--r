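id,enroll_order,arm,outcome,sofa_neuro,age_group
P001,1,0,0,high,young
P002,2,1,0,low,young
P003,3,1,1,low,young
P004,4,0,0,high,old
P005,5,0,0,low,mid
P006,6,0,1,low,young
P007,7,1,0,low,old
P008,8,1,0,low,mid
P009,9,0,1,low,young
P010,10,0,1,low,young
P011,11,1,0,high,old
P012,12,1,1,high,young
P013,13,1,0,low,mid
P014,14,0,1,high,young
P015,15,0,1,high,young
P016,16,1,1,high,old
P017,17,1,0,low,old
P018,18,1,0,low,old
P019,19,0,1,high,old
P020,20,0,1,low,old
P021,21,1,1,low,old
P022,22,0,0,high,mid
P023,23,0,0,low,young
P024,24,1,1,low,old
P025,25,1,0,low,young
P026,26,0,0,low,young
P027,27,1,1,low,young
P028,28,1,1,low,old
P029,29,1,1,low,mid
P030,30,1,1,low,mid
P031,31,1,0,low,young
P032,32,0,1,high,mid
P033,33,0,0,low,young
P034,34,0,0,high,mid
P035,35,0,0,high,old
P036,36,1,1,high,old
P037,37,0,1,high,young
P038,38,1,1,high,mid
P039,39,1,0,low,old
P040,40,0,0,high,old
P041,41,1,1,high,young
P042,42,1,0,high,young
P043,43,1,0,low,mid
P044,44,1,0,low,old
P045,45,1,0,low,old
P046,46,0,0,low,mid
P047,47,1,0,high,mid
P048,48,1,0,low,young
P049,49,1,0,high,mid
P050,50,1,0,high,old
P051,51,1,1,low,mid
P052,52,1,0,low,young
P053,53,0,0,low,mid
P054,54,0,0,low,mid
P055,55,0,1,low,young
P056,56,0,0,high,young
P057,57,0,1,high,young
P058,58,0,0,high,old
P059,59,0,1,low,old
P060,60,1,0,low,old
P061,61,1,0,high,young
P062,62,0,1,low,young
P063,63,0,0,low,young
P064,64,1,0,low,young
P065,65,1,0,high,old
P066,66,1,0,low,mid
P067,67,0,0,high,old
P068,68,0,1,low,old
P069,69,0,0,high,mid
P070,70,0,0,low,young
P071,71,1,0,high,mid
P072,72,1,0,low,old
P073,73,0,0,low,mid
P074,74,0,0,low,young
P075,75,1,0,high,young
P076,76,1,0,low,young
P077,77,0,0,high,old
P078,78,1,0,low,mid
P079,79,1,0,low,old
P080,80,1,0,high,young
P081,81,0,1,low,mid
P082,82,1,1,low,old
P083,83,1,0,high,old
P084,84,1,0,low,young
P085,85,0,0,low,young
P086,86,1,0,low,mid
P087,87,1,0,high,old
P088,88,0,0,high,mid
P089,89,1,1,low,mid
P090,90,1,0,low,young
P091,91,1,0,low,mid
P092,92,0,0,low,young
P093,93,1,1,low,young
P094,94,0,0,low,young
P095,95,0,0,low,old
P096,96,1,1,low,old
P097,97,1,0,low,old
P098,98,1,1,high,young
P099,99,0,0,high,old
P100,100,1,0,low,old
P101,101,0,0,low,young
P102,102,0,1,low,mid
P103,103,0,0,low,mid
P104,104,1,0,high,mid
P105,105,0,0,high,old
P106,106,0,0,high,mid
P107,107,1,0,high,mid
P108,108,0,1,low,old
P109,109,1,0,high,old
P110,110,1,0,high,mid
P111,111,1,0,low,mid
P112,112,0,0,low,young
P113,113,1,1,low,old
P114,114,0,1,low,old
P115,115,1,0,high,mid
P116,116,0,0,low,mid
P117,117,1,0,high,old
P118,118,0,0,low,old
P119,119,1,0,high,young
P120,120,1,1,high,old
P121,121,0,0,high,old
P122,122,0,0,high,mid
P123,123,0,0,low,mid
P124,124,0,1,low,old
P125,125,0,0,high,young
P126,126,0,0,low,young
P127,127,0,0,high,mid
P128,128,0,0,low,old
P129,129,0,1,high,young
P130,130,1,0,high,young
P131,131,0,0,low,mid
P132,132,1,1,low,old
P133,133,0,1,high,old
P134,134,1,0,high,old
P135,135,0,0,low,mid
P136,136,0,1,low,old
P137,137,1,0,high,old
P138,138,1,0,high,old
P139,139,0,0,low,old
P140,140,0,0,high,mid
P141,141,0,0,high,mid
P142,142,1,1,low,old
P143,143,0,1,low,mid
P144,144,0,1,low,old
P145,145,0,0,low,mid
P146,146,0,1,high,young
P147,147,1,0,high,young
P148,148,0,0,high,young
P149,149,1,0,high,mid
P150,150,0,0,low,mid
P151,151,1,0,low,young
P152,152,1,0,low,mid
P153,153,1,1,high,young
P154,154,1,0,low,old
P155,155,1,0,low,young
P156,156,0,0,high,mid
P157,157,1,1,high,old
P158,158,0,0,low,young
P159,159,1,0,low,young
P160,160,1,1,low,mid
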