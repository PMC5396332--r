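zone,region,clusters,children,diarrhoea,ari,stunting
North East (Puntland),Bari,9,756,535,497,201
North East (Puntland),Mudug,61,6188,783,765,804
North East (Puntland),Nugaal,24,1673,384,422,383
North West (Somaliland),Awdal,26,862,51,58,7
North West (Somaliland),Sanaag,14,412,23,54,3
North West (Somaliland),Sool,3,142,25,48,18
North West (Somaliland),Togdheer,12,673,435,849,362
North West (Somaliland),Woqooyi Galbeed,23,2465,768,1128,1378
South Central,Bakool,75,3534,543,1087,1150
South Central,Banadir,1,51,39,14,0
South Central,Bay,98,5568,1236,1876,2133
South Central,Galgaduud,77,5831,1342,1710,1908
South Central,Gedo,111,6985,1048,1851,1999
South Central,Hiraan,142,10743,947,1578,2260
South Central,Juba Dhexe,77,5253,967,1463,2734
South Central,Juba Hoose,71,5560,1514,1617,1553
South Central,Shabelle Dhexe,101,7650,878,1587,2414
South Central,Shabelle Hoose,141,9432,1123,2335,3432
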