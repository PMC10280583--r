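sample_id,         1100,         1144,         1188,         1232,         1276,         1320,         1364,         1408,         1452,         1496,         1540,         1584,         1628,         1672,         1716,         1760,         1804,         1848,         1892,         1936,         1980,         2024,         2068,         2112,         2156,         2200,         2244,         2288,         2332,         2376,         2420,         2464,target:moisture,target:oil,target:protein,target:starch
SYN001,0.219852276356,0.231931516398,0.245670036565,0.239121752123,0.229638803963,0.251038058587,0.321594501579,0.434659433803,0.535781508888,0.580644379018,0.557286811598,0.450804098883,0.327913250635,0.277912566932,0.269674929605,0.255079065701,0.238737253323,0.249704854171,0.277322913924,0.314557602673,0.386802420115,0.537962721203,0.721967163517,0.765953237698,0.642554203438,0.559212203862,0.619365870973,0.668023940704,0.540980929893,0.331711021887,0.236706956192,0.216761428778,11.2296441036,3.39489317104,8.94816445504,65.7494866229
SYN002,0.208778401987,0.220974989766,0.234974492721,0.228221184792,0.218684593192,0.23901040016,0.305356857901,0.412189860436,0.507140762351,0.550516385742,0.530054231544,0.429709772539,0.312436600659,0.267306889955,0.262217298415,0.247659285599,0.228002790957,0.235504541564,0.260933916118,0.295235146883,0.363922900085,0.508902685827,0.686429180224,0.730246254902,0.612422782309,0.532515701773,0.59179159552,0.643092356378,0.524044818037,0.318197279244,0.225545372417,0.206293669215,10.1109437229,3.83105587634,8.32873482272,63.0095732892
SYN003,0.214072245924,0.226107473916,0.239735496867,0.23305626908,0.224191466848, 0.2455846853,0.314195612282,0.424054647847,0.522276372106,0.566940865734,0.546209398507,0.442574072352,0.321159114222,0.272782974211,0.265060787814,0.251089114991,0.232157292523,0.241533919532,0.267448643151,0.302436322971,0.372762295158,0.523507286013,0.707914257719,0.754444510716,0.631880827406,0.548603536481,0.610758496954,0.661523640978,0.536323012536,0.326611073381,0.230899901292,0.211725337062,10.2580280403,3.55165568056,8.44500726135, 65.398100275
SYN004,0.21925805401,0.231153755125,0.244145459381,0.237790390435,0.229585967908,0.250689794166,0.320613156067,0.432900826592,0.533230262889,0.579546739246,0.558159319743,0.45223146424,0.328165183088,0.278982494079,0.269718275954,0.254823489104,0.237214611386,0.247207776537,0.273709091731,0.310363285563,0.384027173815,0.537909457781,0.723884532376,0.769347381208,0.645656245873,0.561818015344,0.621641584063,0.670380848488,0.542100761498,0.331905502064,0.236762482324,0.216295174779,10.5576787056,3.40004287722,9.19327010709,66.1094864689
SYN005,0.214724206284,0.226726153749,0.240358308814,0.233717506252,0.224844386228,0.245510898758,0.31549684797,0.426377084392,0.524962116528,0.567825151117,0.54584248811,0.441807839551,0.320236804057,0.271259414161,0.263963124756,0.250631341442,0.233574760837,0.243369091127,0.270619262009,0.305929459295,0.374691264321,0.522278018608,0.705595190857,0.751953501733,0.629375597627,0.546316101549,0.60868085777,0.660475673077,0.535542792681,0.325801878957,0.231928102471,0.211391818979,10.8720905313,3.50884866953, 8.0530688183, 65.295406699
SYN006,0.215544509731,0.227014753554,0.241061551874,0.234372634759,0.225281136706,0.246692089692,0.315546410087,0.425890167663,0.524089440676,0.569466923011,0.548793370379,0.444513997679,0.32273809071,0.274661778775,0.267186815239,0.252165113074,0.234125875866,0.243069234517,0.269168570407,0.304143138401,0.375669852019,0.526519331973,0.710927577763,0.756540287859,0.634197352569,0.551437444877,0.612185968382,0.662251198886,0.537430114839,0.327558226541,0.232232131667,0.212882951106,10.3661403749,3.58954652685,8.69840290261,65.2997314192
SYN007,0.212875326073,0.225136590866,0.238021684231,0.231846703404,0.222532778628,0.243538300613,0.312333271478,0.420613827654,0.51780739794,0.562665370659,0.541886865113,0.439369869589,0.319015108526,0.271892477203,0.265197615267,0.250262041574,0.231581224972,0.240222757236,0.265988222177,0.301106585718,0.372057759143,0.521252991517,0.702721645797,0.747202520628,0.626390804542,0.54529657498,0.604497900557,0.654347872766,0.531654063239,0.323896954193,0.230181351659,0.21037303985,10.2155467228,3.62702981631,8.71924277463,64.3554670304
SYN008,0.210608274655,0.22182766971,0.234229307119,0.228581341071,0.220339476502,0.241158617147,0.309212805978,0.416782409579,0.513552054001,0.558127360479,0.538127716847,0.436186986042,0.316156178669,0.267673407528,0.25917254286,0.244926673339,0.22811067564,0.237255293858,0.262121794411,0.297136629846,0.367570079659,0.516063829592,0.698098723822,0.743003910897,0.623189527776,0.541669395358,0.600841791316,0.648395635998,0.523610406076,0.319980270404,0.227491214974,0.208370966361,9.97258246403,3.24282932109,8.60822550042,64.2237504175
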