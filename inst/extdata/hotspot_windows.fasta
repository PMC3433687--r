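>AT1G01540.1|98
RVVFSDRVSSGESRGTA
>AT1G07985.1|126
KVVGSSSPTNIHSKSWR
>AT1G08680.1|184
GLHAKASSFVYSPGRFS
>AT1G20440.1|86
QEKTEEDEENKPSVIEKLHRSNSSSSSSSDE
>AT1G26540.1|321
HLRSFLNSKEISETPTKAK
>AT1G27500.1|29
ELQSSNQSPSRQSFGSYGD
>AT1G29220.1|76
GVGASSSAHGTPRSLDN
>AT1G29350.1|100
RYAGRSGSTHFSSTDSG
>AT1G35580.1|38
SFDERSMSELSTGYSRH
>AT1G35580.1|57
IHDSPRGRSVLDTPLSSARN
>AT1G45688.1|12
AASSPARSPRRPVYYVQSPSRDSHDG
>AT1G55310.1|0
MRGRSYTPSPPRGYGRR
>AT1G59710.1|191
FRQESTDSLAVGSPPKS
>AT1G59870.1|32
EDIFSSGSRRTQSVNDD
>AT1G62830.1|817
ERKSLSQEGESMISSLKA
>AT1G66680.1|31
SLASDDDRSIAADSWSIKSEYGSTLD
>AT1G73200.1|306
VQVISRSWSHSSHASDV
>AT1G76920.1|174
ALYYSGTVVANQWLKFSSNL
>AT1G80530.1|265
RSNAKSSPLGSSDNLAK
>AT2G01190.1|378
RVYSDDERSDHGVQAGYRKPPTPRS
>AT2G23350.1|637
SQGSEGNKSGSPSDLLASLSIND
>AT2G26730.1|628
LRQSSDDPSKGSEGQTPPGESRTP
>AT2G29210.1|387
RRRSPSPLYRRNRSPSPLYRRN
>AT2G31650.1|477
MRKFTSLTDHSASALYK
>AT2G35030.1|107
NVVTWTAMVSGYLRSKQL
>AT2G35350.1|185
GEISRSNSAGVHFSAPL
>AT2G35880.1|104
YTDITRKSIDATTSKTS
>AT2G37340.1|198
MDDSLSPRARDRSPVLDDEGSPKIIDGSPPPSPKLQKEVGSDRDGGSPQDNGRNSVVSPVVGAGGDSSKED
>AT2G41705.1|56
RRRHSAGRSSRLSADDF
>AT2G41720.1|526
KADSVTFTILISGSCRM
>AT2G41740.1|842
NKKSPDTSPTRRSTSSN
>AT2G43680.1|122
VPRTLSPKPPSPRAEVPRSLSPKP
>AT2G45540.1|1608
SSERSSGNSVTLDSGSQ
>AT2G46170.1|21
KIHHHDSSSSSESEYEK
>AT2G46495.1|397
KRLLTFNISGSPFSPRF
>AT3G05090.1|365
EVQSPKTVFQRGGSFLAGNLSFNRARVSLEG
>AT3G07790.1|114
KTQTPGSTFLRNFTPLD
>AT3G13570.1|162
GYNSPPAKRHQSRSVSPQD
>AT3G13990.1|489
RVSRSDSPVSAVSEPQL
>AT3G17420.1|55
VTQSPRFTEEIKEISVDHGSSNNN
>AT3G23100.1|220
EEEESTDKAESFESGRS
>AT3G27960.1|570
CGPYHPDTLAVYSNLAGTYDAM
>AT3G29310.1|319
NRHDLTSSAEDDSVDGD
>AT3G29390.1|506
PPRSKTMSPLSSKSMLP
>AT3G48530.1|8
IMRSESLGHRSDVSSPEA
>AT3G52400.1|4
LSGSFKTSVADGSSPPHSHNIEMSKAK
>AT3G52930.1|28
ADESTGTIGKRLASINV
>AT3G53500.1|169
RDQSLSPDRKVIDASPKRGSDYDGSPKE
>AT3G55460.1|0
MRRYSPPYYSPPRRGYG
>AT3G55460.1|170
DSRSRYRSRSYSPAPRR
>AT3G55460.1|197
ENYSRRSYSPGYEGAAA
>AT3G56510.1|228
RQKKSIENETSQSKPGL
>AT3G58940.1|108
QRGVSDLYLFTDFSDED
>AT3G61860.1|243
RQRSPGYDRYRSRSPVP
>AT3G62280.1|87
LKMTYLSPYLDSLSPNF
>AT4G05150.1|260
EVSTLSDPGSPRRDVPSPYG
>AT4G07523.1|0
MPLSYSSPSSSEERSDD
>AT4G11740.1|309
RAASGSLAPPNADRSRSGSPEE
>AT4G13510.1|483
VEPRSPSPSGANTTPTP
>AT4G25160.1|309
TRFSWSGMGVDTTHSRAS
>AT4G25580.1|152
GAPTLTPHNTPVSLLSATE
>AT4G31580.1|156
RRRSPSPPPARGRSYSRSPPPYRAR
>AT4G31700.1|227
RSESLAKKRSRLSSAAAKPSVTA
>AT4G32250.1|9
PDDTEYEIIEGESESALAAGTSPWM
>AT4G35785.1|37
RSRSRSLPRPVSPSRSR
>AT4G38600.1|1362
EGKITSLDDLSTTAAKV
>AT4G39680.1|307
AGDSEKLNLDRSSGDESMED
>AT5G02240.1|228
GSKPEGTSTPTKDFKAL
>AT5G04930.1|36
DLGSKRIRHGSAGADSEMLSMSQKE
>AT5G06210.1|129
DPAVIAATRTTETSKSD
>AT5G18660.1|367
AAESMLILDPETGEYSEEK
>AT5G21160.1|366
SAETIGDGDKDSPKSITSGDN
>AT5G41600.1|19
HGHGDSSSLSDSDDDKK
>AT5G47690.1|1270
HLESDMDKNVSLDSHDENSDQE
>AT5G52040.1|188
RRRSPSPYRRERGSPDYGRGASPVAHKRERTSPDYGRGRRSPSPYKRARLSPDY
>AT5G52040.1|333
GRGYDGADSPIRESPSRSPPA
>AT5G57110.1|15
DVESGKSEHADSDSDTF
>AT5G62820.1|24
RFHSPLSDAGDLPESRYVSPEGSPFK
>AT5G64200.1|269
PERRSNERSPSPGSPAP
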