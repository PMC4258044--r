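"subject","rater","replicate","value"
"1","1","1",4.59149837318681
"2","1","1",2.81608935940171
"3","1","1",-0.370602052594768
"4","1","1",6.41545524338341
"5","1","1",1.9424852670825
"6","1","1",11.4249180785412
"7","1","1",2.80159167541226
"8","1","1",8.31543359619971
"9","1","1",8.24998894736747
"10","1","1",4.96516327310798
"11","1","1",11.4305283108173
"12","1","1",9.0347913025073
"13","1","1",9.93920237495921
"14","1","1",1.50521434240747
"15","1","1",10.6300910725952
"16","1","1",4.14137512926195
"17","1","1",5.5219997554165
"18","1","1",4.84084897408229
"19","1","1",5.77520209858299
"20","1","1",11.2699453973986
"21","1","1",9.40412992301123
"22","1","1",4.9751152705356
"23","1","1",2.21954305641803
"24","1","1",8.56234039438299
"1","2","1",3.75004244971493
"2","2","1",4.46325076483054
"3","2","1",-0.484170728222959
"4","2","1",6.38476574781887
"5","2","1",3.98960492260318
"6","2","1",10.446059161672
"7","2","1",4.65748011967792
"8","2","1",7.84462368572595
"9","2","1",7.3121639809768
"10","2","1",5.44319773252893
"11","2","1",9.21144798682904
"12","2","1",7.25522064030676
"13","2","1",9.13510971724402
"14","2","1",2.32273343657783
"15","2","1",9.01937866619609
"16","2","1",3.73265871308218
"17","2","1",3.83992542940508
"18","2","1",3.47949884052496
"19","2","1",5.01092911960598
"20","2","1",9.88973289360441
"21","2","1",6.88103130565401
"22","2","1",2.76460972385652
"23","2","1",1.72040007327069
"24","2","1",7.43704429295227
"1","3","1",5.94297645408094
"2","3","1",5.57287394883318
"3","3","1",-1.02253324668969
"4","3","1",7.11824101112107
"5","3","1",3.35011867452439
"6","3","1",13.0733641502761
"7","3","1",2.86945764656208
"8","3","1",6.94032267628446
"9","3","1",6.61920997219626
"10","3","1",5.33831611835828
"11","3","1",9.52745040859284
"12","3","1",8.20378486897278
"13","3","1",7.70924955935373
"14","3","1",2.20397849663262
"15","3","1",9.64724495719999
"16","3","1",5.40707896468355
"17","3","1",5.79170877443994
"18","3","1",5.3441571038492
"19","3","1",7.05166585097206
"20","3","1",10.8417782360743
"21","3","1",10.0518638511011
"22","3","1",2.42572854761216
"23","3","1",2.06133022083875
"24","3","1",7.79415984341904
"1","4","1",3.55488894461929
"2","4","1",3.98223349134422
"3","4","1",-2.72342704152465
"4","4","1",7.00245960899152
"5","4","1",1.42161028674766
"6","4","1",12.8786432535069
"7","4","1",3.358297460676
"8","4","1",9.83605925791956
"9","4","1",7.1030658236571
"10","4","1",6.6207777360951
"11","4","1",9.09534225236902
"12","4","1",6.95556297908534
"13","4","1",8.49231393509934
"14","4","1",2.75558710817708
"15","4","1",8.25581228763842
"16","4","1",6.34709621546895
"17","4","1",3.60402163802994
"18","4","1",4.9645105277114
"19","4","1",4.13415865669276
"20","4","1",11.8298476732993
"21","4","1",9.15685119183929
"22","4","1",3.14451559425115
"23","4","1",1.35862522452444
"24","4","1",8.72005638935167
"1","5","1",2.72407634922713
"2","5","1",3.16630229432041
"3","5","1",-0.936225252776784
"4","5","1",7.09109292194221
"5","5","1",2.73038899724003
"6","5","1",12.9317696141463
"7","5","1",3.42867831896715
"8","5","1",8.61408954278006
"9","5","1",7.44122202321536
"10","5","1",5.67853156168936
"11","5","1",10.35935341866
"12","5","1",6.48014784966685
"13","5","1",9.25585874348631
"14","5","1",1.51651016851977
"15","5","1",7.25771936389438
"16","5","1",4.74477817655578
"17","5","1",3.94853128365308
"18","5","1",5.20887131545856
"19","5","1",2.90276369709176
"20","5","1",10.2471289150488
"21","5","1",9.86216884768687
"22","5","1",3.93355135683595
"23","5","1",0.456200347658325
"24","5","1",9.48812736162323
"1","6","1",4.00783931292483
"2","6","1",2.91166529340181
"3","6","1",-0.311548343397034
"4","6","1",6.58638320406243
"5","6","1",2.12859669430977
"6","6","1",12.3588487825377
"7","6","1",4.23881806169429
"8","6","1",8.7884474117863
"9","6","1",6.48358412047036
"10","6","1",7.16915691397077
"11","6","1",8.72348943338722
"12","6","1",8.88356734408926
"13","6","1",8.46847051222279
"14","6","1",0.527411947802128
"15","6","1",11.8363745567764
"16","6","1",4.59950118494236
"17","6","1",3.57966826092685
"18","6","1",3.22403894348607
"19","6","1",5.12860071334717
"20","6","1",11.6864639984867
"21","6","1",11.0964146535406
"22","6","1",3.78010276246985
"23","6","1",1.10818472885833
"24","6","1",9.12628130645473
"1","7","1",3.52711632706358
"2","7","1",5.63573575741976
"3","7","1",-0.545493987088125
"4","7","1",5.40035226454805
"5","7","1",1.92576326061845
"6","7","1",10.608828571101
"7","7","1",3.63521849890989
"8","7","1",7.6722976996084
"9","7","1",7.27031582881791
"10","7","1",4.75715375998908
"11","7","1",9.35178731981548
"12","7","1",5.77322496423041
"13","7","1",9.1649604428901
"14","7","1",0.582149376291152
"15","7","1",9.8760349367614
"16","7","1",4.38928613745287
"17","7","1",4.01938874002059
"18","7","1",4.81988603776735
"19","7","1",6.09954048382871
"20","7","1",10.3757705836416
"21","7","1",10.6164763206452
"22","7","1",4.13328499199019
"23","7","1",2.03615306411433
"24","7","1",8.04203344939621
"1","8","1",3.79459685557585
"2","8","1",4.29269712533775
"3","8","1",-1.60678147590633
"4","8","1",7.38643943659101
"5","8","1",2.31020819250826
"6","8","1",11.483938870861
"7","8","1",3.70818783788087
"8","8","1",8.48679115568412
"9","8","1",6.27719739198412
"10","8","1",6.72393337327989
"11","8","1",8.17665819405862
"12","8","1",7.95031283911747
"13","8","1",8.55778249193542
"14","8","1",0.331282930950732
"15","8","1",6.83382725977406
"16","8","1",6.18111953317226
"17","8","1",3.6728455414739
"18","8","1",5.03234155038041
"19","8","1",4.16183708747229
"20","8","1",10.3877051144629
"21","8","1",9.87295666859727
"22","8","1",3.97899138740883
"23","8","1",1.92762910278044
"24","8","1",9.02351710618724
"1","9","1",4.9591680770566
"2","9","1",4.53302350046335
"3","9","1",-0.991809231342977
"4","9","1",4.95468007812183
"5","9","1",2.53181408495817
"6","9","1",12.3310621482042
"7","9","1",3.64346898482192
"8","9","1",8.17683569750556
"9","9","1",6.5567810436009
"10","9","1",5.05580702214257
"11","9","1",7.4720842414472
"12","9","1",6.8375366743366
"13","9","1",9.24354755132882
"14","9","1",1.98596808317861
"15","9","1",10.0162477873168
"16","9","1",6.22861958056795
"17","9","1",3.49855757436871
"18","9","1",6.83052492013223
"19","9","1",4.49826039983576
"20","9","1",11.5270089761164
"21","9","1",11.2668406312835
"22","9","1",5.77341428595672
"23","9","1",0.655585031493944
"24","9","1",7.95661119358633
"1","10","1",4.02731076298164
"2","10","1",4.0317202483766
"3","10","1",-2.26556428138038
"4","10","1",6.87577732925323
"5","10","1",2.96493222636067
"6","10","1",12.022512136174
"7","10","1",2.12894431315871
"8","10","1",8.42282467834485
"9","10","1",6.7251486014171
"10","10","1",5.41518579566099
"11","10","1",7.40490505403549
"12","10","1",7.12082088903416
"13","10","1",9.69717767998386
"14","10","1",2.32981648520701
"15","10","1",8.91580321490746
"16","10","1",6.0612844176585
"17","10","1",3.83347652911112
"18","10","1",5.51875947982624
"19","10","1",4.30278125128958
"20","10","1",10.844235735905
"21","10","1",10.5929209640289
"22","10","1",5.15819277025403
"23","10","1",1.26791824303334
"24","10","1",8.27124610901557
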