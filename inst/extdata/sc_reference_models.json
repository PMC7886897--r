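[
  {
    "soma.Nav1.1": 0.0920045050952337,
    "soma.Nav1.6": 0.00347111112664291,
    "soma.Kv3.4": 0.0433043796211328,
    "soma.Kv4.3": 0.000448053636818491,
    "soma.Kir2.3": 1.94290756398031e-05,
    "soma.Kv7": 0.000277407844666525,
    "soma.KCa1.1": 0.00880081543727248,
    "soma.KCa2.2": 2.6966164735394e-05,
    "soma.Cav2.1": 0.00210332549372383,
    "soma.Cav3.2": 0.000637889141086417,
    "soma.HCN1": 0.000313308256244199,
    "prox_dend.Kv3.4": 0.00451144516734747,
    "prox_dend.Kv4.3": 0.00155142301503724,
    "prox_dend.Kir2.3": 0.000679035924905016,
    "prox_dend.KCa1.1": 0.000479296821656721,
    "prox_dend.KCa2.2": 2.50258087701921e-05,
    "prox_dend.Cav2.1": 0.00200831731645726,
    "prox_dend.Cav3.2": 0.0016721413410913,
    "prox_dend.Cav3.3": 0.00124314142072182,
    "prox_dend.HCN1": 0.000559081374746009,
    "dist_dend.Kv3.4": 0.00265483998797319,
    "dist_dend.Kv4.3": 0.000448933571897489,
    "dist_dend.Kv7": 3.01612504354115e-05,
    "dist_dend.KCa1.1": 0.00150390282196036,
    "dist_dend.KCa2.2": 5.43724444380138e-06,
    "dist_dend.Cav2.1": 0.000389284278966759,
    "dist_dend.Cav3.2": 0.000196019134205855,
    "dist_dend.Cav3.3": 0.000135104883699462,
    "dist_dend.HCN1": 0.000190149562069252,
    "ais.Nav1.6": 0.645561771593702,
    "ais.Kv3.4": 0.0609282267219457,
    "ais.Kv1.1": 0.0409397803182178,
    "ais.Cav2.1": 0.000158247002008436,
    "axon.Nav1.6": 0.0299210038004785,
    "axon.Kv3.4": 0.0185840319291115,
    "axon.Kv1.1": 0.0521266576070945
  },
  {
    "soma.Nav1.1": 0.148216375699718,
    "soma.Nav1.6": 0.0210044916448078,
    "soma.Kv3.4": 0.0840734029002055,
    "soma.Kv4.3": 0.00123442400915249,
    "soma.Kir2.3": 2.91197517219958e-05,
    "soma.Kv7": 0.00018258494894902,
    "soma.KCa1.1": 0.00571353579822834,
    "soma.KCa2.2": 1.22277882878689e-05,
    "soma.Cav2.1": 0.000525520414792295,
    "soma.Cav3.2": 0.00252396540894362,
    "soma.HCN1": 0.000571728429694522,
    "prox_dend.Kv3.4": 0.00693028028430807,
    "prox_dend.Kv4.3": 0.000540394107944679,
    "prox_dend.Kir2.3": 0.00164423943910018,
    "prox_dend.KCa1.1": 0.00448756547301683,
    "prox_dend.KCa2.2": 1.51380050523144e-06,
    "prox_dend.Cav2.1": 0.000230479505150829,
    "prox_dend.Cav3.2": 0.00333425518778771,
    "prox_dend.Cav3.3": 0.00017509486180242,
    "prox_dend.HCN1": 0.000174685867841198,
    "dist_dend.Kv3.4": 0.00243311507931143,
    "dist_dend.Kv4.3": 0.000203054219771467,
    "dist_dend.Kv7": 2.56929033032277e-05,
    "dist_dend.KCa1.1": 0.00922055257293685,
    "dist_dend.KCa2.2": 8.07747443951333e-06,
    "dist_dend.Cav2.1": 0.00122963954349854,
    "dist_dend.Cav3.2": 5.82206299709886e-05,
    "dist_dend.Cav3.3": 0.000180005185546442,
    "dist_dend.HCN1": 0.00024892778400138,
    "ais.Nav1.6": 0.980922903497063,
    "ais.Kv3.4": 0.227054486721625,
    "ais.Kv1.1": 0.106989524432523,
    "ais.Cav2.1": 0.000150668041726439,
    "axon.Nav1.6": 0.0599501109411426,
    "axon.Kv3.4": 0.0218657356612747,
    "axon.Kv1.1": 0.013942665554251
  },
  {
    "soma.Nav1.1": 0.358549442786566,
    "soma.Nav1.6": 0.0282252201570988,
    "soma.Kv3.4": 0.0206966322441119,
    "soma.Kv4.3": 0.000612484406236844,
    "soma.Kir2.3": 0.00011156832594994,
    "soma.Kv7": 0.000280164355953127,
    "soma.KCa1.1": 0.0208857928543473,
    "soma.KCa2.2": 2.68915817695508e-06,
    "soma.Cav2.1": 0.0015608996774158,
    "soma.Cav3.2": 0.000555664692764928,
    "soma.HCN1": 0.00208432864475023,
    "prox_dend.Kv3.4": 0.000988808211400425,
    "prox_dend.Kv4.3": 0.000545392437786929,
    "prox_dend.Kir2.3": 0.00162287856943165,
    "prox_dend.KCa1.1": 0.00228631578579649,
    "prox_dend.KCa2.2": 1.32858659637038e-05,
    "prox_dend.Cav2.1": 0.000608721771093877,
    "prox_dend.Cav3.2": 0.000192185836771749,
    "prox_dend.Cav3.3": 3.89926933360035e-05,
    "prox_dend.HCN1": 0.000321216151670101,
    "dist_dend.Kv3.4": 0.00648778957014275,
    "dist_dend.Kv4.3": 0.000440484073171176,
    "dist_dend.Kv7": 8.89041888174226e-06,
    "dist_dend.KCa1.1": 0.00257110165981484,
    "dist_dend.KCa2.2": 2.54421617799295e-06,
    "dist_dend.Cav2.1": 0.000371450146571716,
    "dist_dend.Cav3.2": 0.0019904860148561,
    "dist_dend.Cav3.3": 0.000251287847737521,
    "dist_dend.HCN1": 0.000385598364611426,
    "ais.Nav1.6": 0.266652614855223,
    "ais.Kv3.4": 0.0379265629706889,
    "ais.Kv1.1": 0.122794153092774,
    "ais.Cav2.1": 0.000192028752254981,
    "axon.Nav1.6": 0.0336060863853772,
    "axon.Kv3.4": 0.0609463767437709,
    "axon.Kv1.1": 0.0457795240527314
  },
  {
    "soma.Nav1.1": 0.0319436123989612,
    "soma.Nav1.6": 0.0957357331806036,
    "soma.Kv3.4": 0.0404117380234997,
    "soma.Kv4.3": 0.000142199280684959,
    "soma.Kir2.3": 0.000173612712079404,
    "soma.Kv7": 8.90668995751114e-05,
    "soma.KCa1.1": 0.0128376674269616,
    "soma.KCa2.2": 1.93307767311782e-05,
    "soma.Cav2.1": 0.000745755862783714,
    "soma.Cav3.2": 0.00235415558694747,
    "soma.HCN1": 0.000359161432221074,
    "prox_dend.Kv3.4": 0.000877984150190011,
    "prox_dend.Kv4.3": 0.00234212166286042,
    "prox_dend.Kir2.3": 0.00017310567596597,
    "prox_dend.KCa1.1": 0.00170956078025057,
    "prox_dend.KCa2.2": 2.89504638089655e-06,
    "prox_dend.Cav2.1": 0.00213641751132724,
    "prox_dend.Cav3.2": 0.00186914096254223,
    "prox_dend.Cav3.3": 0.000470794559378937,
    "prox_dend.HCN1": 0.000672849685371601,
    "dist_dend.Kv3.4": 0.00656561629479111,
    "dist_dend.Kv4.3": 0.000835958847635362,
    "dist_dend.Kv7": 5.27327934735571e-05,
    "dist_dend.KCa1.1": 0.00495667064042817,
    "dist_dend.KCa2.2": 1.01238945839335e-05,
    "dist_dend.Cav2.1": 0.000541007375993196,
    "dist_dend.Cav3.2": 0.00199594442979255,
    "dist_dend.Cav3.3": 3.71908396384717e-05,
    "dist_dend.HCN1": 2.6115234863542e-05,
    "ais.Nav1.6": 0.580607614541977,
    "ais.Kv3.4": 0.159441360693423,
    "ais.Kv1.1": 0.0365847921334854,
    "ais.Cav2.1": 0.000508797953843271,
    "axon.Nav1.6": 0.0326355306143295,
    "axon.Kv3.4": 0.0276158373706528,
    "axon.Kv1.1": 0.0209949684065522
  }
]
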