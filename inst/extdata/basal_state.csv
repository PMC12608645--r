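"variable","value"
"glucose_i",4.78816954903164
"g6p",1.28729671551349
"f6p",0.381645690020628
"f16bp",0.0335552695541006
"dhap",0.234813700789843
"gap",0.00784062175525226
"bpg13",0.123682918112639
"pg3",0.190767785078561
"pg2",0.0213458483473471
"pep",0.0398064803271632
"pyruvate",0.245173659905361
"lactate_i",0.191099311157149
"proton_i",6.30957344345928e-05
"glycogen",16.8471632552051
"accoa",0.047004932232106
"citrate",0.268771668172443
"isocitrate",0.0124131536804749
"akg",0.012413153680487
"succinyl_coa",0.0501130518579134
"succinate",0.0278522241426024
"fumarate",0.0525183194046787
"malate",0.173496917094717
"oaa",0.299421511966404
"atp",1.93071916111165
"adp",0.0669586663576416
"amp",0.00232217253065348
"pi",10.4372301405768
"nad_c",0.993744906257082
"nadh_c",0.00425509374290946
"nad_m",2.79715887809486
"nadh_m",2.20284112190514
"fad",0.57365421437795
"fadh2",0.426345785622039
"HIF1A",0.239480216715103
"LDH",1.14927185775373
"PDH",0.84503328309943
"PDK",0.331349007711687
"GLUT",0.878736590402486
"MCT",0.636573842330363
"HK",1.01044966923736
"PFK",1.01044966923736
"MYC",1
"AMPK",0.252813657630709
"p_HIF1A",0.239480216719788
"p_LDH",1.14927185776417
"p_PDH",0.845033283075949
"p_PDK",0.331349007715013
"p_GLUT",0.878736590405534
"p_MCT",0.63657384233429
"p_HK",1.01044966923864
"p_PFK",1.01044966923864
"p_MYC",1
"p_AMPK",0.25281365752443
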