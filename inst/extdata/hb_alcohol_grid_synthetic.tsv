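# Primary-bond shift perturbation grid, alcohol acceptors
# (N-methylacetamide/methanol-like scan). Columns as carboxylate grid;
# synthetic values.
r	angle	value
1.4	90	2.90761508060927
1.6	90	1.91043924196062
1.8	90	1.25524802838011
2	90	0.824756725126274
2.2	90	0.541903783365299
2.4	90	0.356056157505917
2.6	90	0.233945565964832
2.8	90	0.153713190127026
3	90	0.10099676273659
3.2	90	0.0663596017676922
3.4	90	0.0436013653056558
3.6	90	0.0286481384136757
3.8	90	0.0188231682383272
4	90	0.0123677028298367
1.4	100	3.11484766138872
1.6	100	2.04660075012382
1.8	100	1.34471251429997
2	100	0.883539081086302
2.2	100	0.580526543410072
2.4	100	0.381433119165816
2.6	100	0.250619417920037
2.8	100	0.164668691528261
3	100	0.10819504009175
3.2	100	0.0710892070120471
3.4	100	0.0467089373904398
3.6	100	0.0306899587693291
3.8	100	0.0201647398096429
4	100	0.0132491781643239
1.4	110	3.71155009605789
1.6	110	2.4386621871991
1.8	110	1.6023152347024
2	110	1.05279612930243
2.2	110	0.691736348671762
2.4	110	0.454503168045261
2.6	110	0.298629861160007
2.8	110	0.196213800576995
3	110	0.12892165367294
3.2	110	0.0847075625511033
3.4	110	0.0556568345884875
3.6	110	0.0365691461673383
3.8	110	0.0240276411926016
4	110	0.0157872852332562
1.4	120	4.62575126460566
1.6	120	3.03933515766462
1.8	120	1.99698549969564
2	120	1.3121129717918
2.2	120	0.862119655353884
2.4	120	0.566452977850323
2.6	120	0.372186127671323
2.8	120	0.244543711565724
3	120	0.160676667990029
3.2	120	0.105572093721328
3.4	120	0.069365808440816
3.6	120	0.0455765838399386
3.8	120	0.0299459494700659
4	120	0.0196758908656492
1.4	130	5.74718501393287
1.6	130	3.77616963629335
1.8	130	2.48112025060872
2	130	1.6302121702412
2.2	130	1.07112572208078
2.4	130	0.703779749315283
2.6	130	0.462416246137844
2.8	130	0.303829123955688
3	130	0.199629959662279
3.2	130	0.131166230135909
3.4	130	0.0861823543779286
3.6	130	0.0566258418681922
3.8	130	0.0372058293188459
4	130	0.0244459718325296
1.4	140	6.94058988327121
1.6	140	4.56029251044391
1.8	140	2.99632569141359
2	140	1.96872626667345
2.2	140	1.29354533260416
2.4	140	0.849919847074173
2.6	140	0.558437132617785
2.8	140	0.366919342053155
3	140	0.241083186824658
3.2	140	0.158402941214021
3.4	140	0.104078148774024
3.6	140	0.0683842166642107
3.8	140	0.0449316320847634
4	140	0.029522185970394
1.4	150	8.06202363259843
1.6	150	5.29712698907263
1.8	150	3.48046044232668
2	150	2.28682546512285
2.2	150	1.50255139933106
2.4	150	0.987246618539134
2.6	150	0.648667251084306
2.8	150	0.426204754443119
3	150	0.280036478496908
3.2	150	0.183997077628601
3.4	150	0.120894694711137
3.6	150	0.0794334746924644
3.8	150	0.0521915119335435
4	150	0.0342922669372744
1.4	160	8.9762248011462
1.6	160	5.89779995953815
1.8	160	3.87513070731991
2	160	2.54614230761222
2.2	160	1.67293470601318
2.4	160	1.0991964283442
2.6	160	0.722223517595623
2.8	160	0.474534665431848
3	160	0.311791492813997
3.2	160	0.204861608798826
3.4	160	0.134603668563465
3.6	160	0.0884409123650646
3.8	160	0.0581098202110078
4	160	0.0381808725696674
1.4	170	9.57292723581537
1.6	170	6.28986139661343
1.8	170	4.13273342772235
2	170	2.71539935582835
2.2	170	1.78414451127487
2.4	170	1.17226647722364
2.6	170	0.770233960835593
2.8	170	0.506079774480582
3	170	0.332518106395187
3.2	170	0.218479964337882
3.4	170	0.143551565761513
3.6	170	0.0943200997630739
3.8	170	0.0619727215939665
4	170	0.0407189796385996
1.4	180	9.78015981659482
1.6	180	6.42602290477663
1.8	180	4.2221979136422
2	180	2.77418171178837
2.2	180	1.82276727131964
2.4	180	1.19764343888354
2.6	180	0.786907812790798
2.8	180	0.517035275881816
3	180	0.339716383750348
3.2	180	0.223209569582237
3.4	180	0.146659137846297
3.6	180	0.0963619201187273
3.8	180	0.0633142931652822
4	180	0.0416004549730869
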