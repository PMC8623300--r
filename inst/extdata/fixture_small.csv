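# synthetic 25-sheet example collection; seed: 421
id,year,doy,latitude,longitude,elevation,spring_tmax,winter_ppt,manual_buds,manual_flowers,manual_immature,manual_mature,pred_buds,pred_flowers,pred_immature,pred_mature,stage,pi_true
SYN00001,1919,155,40.2372390320525,-122.050094049773,397.530894586816,23.6353438657348,265.214006001477,2,15,3,0,1,5,1,0,1.0662885310594,2.0662885310594
SYN00002,1930,223,36.3702015765011,-118.44826979225,2639.51977811521,8.2609636834201,1466.14569066347,18,10,0,0,4,0,0,0,0.322441693162546,1.32244169316255
SYN00003,1947,104,39.7926959949546,-119.569996160339,265.354485949501,24.9011829755883,971.315055826906,4,41,22,6,0,16,6,1,1.67752129607834,2.67752129607834
SYN00004,1916,177,37.3883001678623,-120.256784884492,1811.2099056365,15.4330511532954,791.960928358703,0,19,9,4,0,1,3,1,1.67362409387715,2.67362409387715
SYN00005,1924,169,40.5710661094636,-118.271624293644,1719.40408231458,14.5374632734524,697.598991467592,54,113,14,0,5,27,5,0,1.01557509088889,2.01557509088889
SYN00006,2008,235,39.6970408121124,-118.329468357493,3070.96962037031,3.34369290066434,342.166375244167,0,9,7,3,0,2,2,0,1.73538294900209,2.73538294900209
SYN00007,1976,180,40.9023116976023,-119.006984080537,2929.87715873169,7.87524027299175,1355.57485928714,48,43,2,0,11,6,0,0,0.690695914439857,1.69069591443986
SYN00008,1939,208,39.5997550906613,-122.451896423241,2302.25242036395,10.0537217192675,391.428434979662,23,75,13,0,4,13,5,0,1.12578851776198,2.12578851776198
SYN00009,1919,165,38.6787444483489,-118.684693199117,879.09312119009,17.8169017362457,976.790839812479,0,9,13,12,0,2,1,7,2.17423224938102,3.17423224938102
SYN00010,1949,234,36.7564604477957,-120.874581695301,2709.25118440064,8.46375205525201,567.271529703126,45,15,0,0,5,1,0,0,0.0818613606970757,1.08186136069708
SYN00011,1945,180,37.4084588740952,-121.262499395874,1278.94895026693,16.8821008881582,1541.02754509852,57,49,1,0,7,10,0,0,0.640046278014779,1.64004627801478
SYN00012,2011,169,37.6043634153903,-119.099324054434,2047.36731403973,14.6714889736688,821.193852598997,5,63,32,5,0,14,7,3,1.51566495699808,2.51566495699808
SYN00013,1943,181,37.2331113792025,-121.100349110086,680.250752880238,22.0142612622706,1852.34877385632,0,2,14,35,0,1,5,12,2.47362975915894,3.47362975915894
SYN00014,2000,221,39.9234329671599,-119.407417268027,2940.57833102997,9.21473607626723,182.976848408399,0,6,17,29,0,0,6,6,2.3322322703898,3.3322322703898
SYN00015,1931,184,40.354541446548,-120.281494390336,1332.78155907756,18.4357417821775,442.988677703989,0,3,32,70,0,0,8,17,2.69210133003071,3.69210133003071
SYN00016,1959,197,38.052052043844,-122.369972696993,2043.93415108789,10.4382148686316,384.507492984061,16,56,3,1,2,11,1,1,1.09780490468256,2.09780490468256
SYN00017,1969,225,37.4074822021648,-119.162700567278,1921.09093636973,12.7924863164057,658.561563367646,0,6,24,25,0,1,7,6,2.21712932386436,3.21712932386436
SYN00018,1961,136,38.9115705355071,-118.211358841509,1686.45393578336,18.6419773078762,720.638818045502,10,24,0,0,3,6,0,0,0.816330956993625,1.81633095699362
SYN00019,1925,175,36.3092204034328,-119.007940825541,2140.24950795574,14.0684609664646,1565.80380154746,6,44,29,4,3,14,9,1,1.615173361497,2.615173361497
SYN00020,1934,138,38.6534842420369,-118.726778116776,700.495750363916,20.9512855443312,275.652995302138,66,30,1,0,8,9,0,0,0.386059930315241,1.38605993031524
SYN00021,1914,227,40.9686139724217,-119.971314095426,3003.42200230807,5.7815964968923,467.970909103537,25,4,0,0,2,0,0,0,0.132102472241968,1.13210247224197
SYN00022,1957,222,36.3605005210266,-120.559777593706,3007.35916331178,6.00692155830249,469.627810262692,3,7,1,0,0,1,1,0,0.937247097026557,1.93724709702656
SYN00023,2010,194,37.3954262482002,-121.45762742369,2232.956563076,9.38642232421751,441.523716228158,8,50,8,1,1,12,2,0,1.24484922434203,2.24484922434203
SYN00024,1936,188,37.3839150299318,-120.182650172734,1185.29930091463,18.4396209316813,406.728483199951,0,21,26,14,0,2,6,3,1.92298490018584,2.92298490018584
SYN00025,1906,124,38.4143547038548,-119.83474750293,424.921509204432,24.0270140208635,570.317004308546,34,37,5,0,8,11,3,0,0.881822851253673,1.88182285125367
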