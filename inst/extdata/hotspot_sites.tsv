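protein_id	window_start	site_positions
AT1G01540.1	98	102,106,107,110
AT1G07985.1	126	130,132,134,138
AT1G08680.1	184	190,191,194,195
AT1G20440.1	86	89,98,108,113
AT1G26540.1	321	324,328,334,336
AT1G27500.1	29	32,33,36,44
AT1G29220.1	76	80,82,86,89
AT1G29350.1	100	105,107,108,112
AT1G35580.1	38	43,45,48,49
AT1G35580.1	57	60,65,69,72,73
AT1G45688.1	12	15,19,29,31,34
AT1G55310.1	0	4,5,6,8
AT1G59710.1	191	195,196,198,203
AT1G59870.1	32	36,39,42,44
AT1G62830.1	817	820,822,830,831
AT1G66680.1	31	34,44,46,53
AT1G73200.1	306	312,314,316,317
AT1G76920.1	174	177,178,180,190
AT1G80530.1	265	270,271,275,276
AT2G01190.1	378	381,386,394,399
AT2G23350.1	637	640,647,649,656
AT2G26730.1	628	631,632,636,639,648
AT2G29210.1	387	390,392,395,400,402,405
AT2G31650.1	477	481,482,484,487,489
AT2G35030.1	107	110,112,116,121
AT2G35350.1	185	188,190,192,198
AT2G35880.1	104	108,111,116,117
AT2G37340.1	198	201,203,210,218,225,229,238,244,252,255,264,265
AT2G41705.1	56	60,64,65,68
AT2G41720.1	526	529,531,537,539
AT2G41740.1	842	845,848,854,855
AT2G43680.1	122	125,127,132,142
AT2G45540.1	1608	1612,1613,1618,1621
AT2G46170.1	21	27,28,29,30,31
AT2G46495.1	397	401,405,407,410
AT3G05090.1	365	368,378,385,392
AT3G07790.1	114	117,120,121,127
AT3G13570.1	162	165,173,175,177
AT3G13990.1	489	493,495,498,501
AT3G17420.1	55	58,62,69,74,75
AT3G23100.1	220	224,225,230,233
AT3G27960.1	570	573,577,581,582,588
AT3G29310.1	319	324,325,326,331
AT3G29390.1	506	511,513,516,517
AT3G48530.1	8	11,13,18,21,22
AT3G52400.1	4	7,17,21,27
AT3G52930.1	28	31,32,34,41
AT3G53500.1	169	172,174,183,188,190,193
AT3G55460.1	0	3,4,7,9
AT3G55460.1	170	175,177,179,181
AT3G55460.1	197	203,204,205,208
AT3G56510.1	228	232,237,238,240
AT3G58940.1	108	112,115,118,121
AT3G61860.1	243	246,252,254,256
AT3G62280.1	87	90,93,95,98,100
AT4G05150.1	260	263,265,269,276
AT4G07523.1	0	3,5,6,8,9,10
AT4G11740.1	309	312,314,323,325,327
AT4G13510.1	483	487,489,491,495
AT4G25160.1	309	312,314,321,323
AT4G25580.1	152	155,157,161,167
AT4G31580.1	156	159,169,171,173,177
AT4G31700.1	227	230,236,239,240,246
AT4G32250.1	9	12,21,23,29,30
AT4G35785.1	37	40,42,48,50
AT4G38600.1	1362	1366,1367,1372,1373,1374
AT4G39680.1	307	310,318,319,323
AT5G02240.1	228	234,235,236,238
AT5G04930.1	36	39,46,51,57
AT5G06210.1	129	136,138,139,141,142
AT5G18660.1	367	370,378,381,382
AT5G21160.1	366	369,377,380,383
AT5G41600.1	19	24,25,28,30
AT5G47690.1	1270	1273,1280,1283,1288
AT5G52040.1	188	191,201,209,218,219,228,230,232,238
AT5G52040.1	333	336,341,346,348,350
AT5G57110.1	15	18,21,26,28
AT5G62820.1	24	27,30,40,46
AT5G64200.1	269	273,277,279,282
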