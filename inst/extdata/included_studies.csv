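study_id,n,age,space,x,y,z,paradigm,stimuli,contrast
"Anderson et al., 2004",24,"29-31",MNI,,,,T/NT,"word pairs","suppression > recall"
"Bastin et al., 2012",17,"20-32",MNI,,,,DF,"6-letter words","To be forget-forget > To be remember-forget"
"Benoit et al., 2012",18,"23.7",MNI,,,,T/NT,"word pairs","suppression > recall"
"Benoit et al., 2015",16,"22",MNI,,,,T/NT,"Picture","suppression > recall"
"Butler et al., 2010",14,"22.6",MNI,,,,T/NT,"emotion pictures","NT > T (neutral)"
"Depue et al., 2007",16,"19-29",MNI,,,,T/NT,"face-picture pairs","Suppression > recall"
"Depue et al., 2016",21,"21.5",MNI,,,,T/NT,"neutral face pictures","Suppression > recall"
"Gagnepain et al., 2014",24,"22.",MNI,,,,T/NT,"word-object pairs","Suppression > recall"
"Gagnepain et al., 2017",22,"18-35",MNI,,,,T/NT,"face-scene pairs","NT > T"
"Gamboa et al., 2018",31,"27.5",MNI,,,,DF,"vocal words","To be Forget > to be remember"
"Hanslmayr et al., 2012",22,"23.05",MNI,,,,DF,"words","To be Forget > to be remember"
"Marchewka et al., 2016",18,"22.02",MNI,,,,DF,"emotional pictures","TBF-F > TBR-F"
"Noreen et al., 2016",22,"18-29",MNI,,,,T/NT,"word-autobiographic-memory pairs","no-think > think"
"Nowicka et al., 2011",16,"26.6",MNI,,,,DF,"emotional pictures","TBF > TBR for neutral pictures"
"Reber et al., 2002",12,"20",MNI,,,,DF,"faces","TBF > TBR"
"Rizio et al., 2013",24,"21.11",MNI,,,,DF,"words","TBF > TBR"
"Sacchet et al., 2017",16,"31.7",MNI,,,,T/NT,"word-pairs","no-think > think"
"Wang et al., 2019",20,"23.6",MNI,,,,DF,"pictures (scene, faces, objects)","TBF > TBR"
"Wierzba et al., 2018",24,"24.6",MNI,,,,DF,"neutral/affective words","TBF > TBR"
"Wylie et al., 2008",11,"26",MNI,,,,DF,"word pairs","TBF > TBR"
"Yang, T. et al., 2016",21,"22.19",MNI,,,,DF,"word pairs","TBF > TBR (neutral words)"
"Yang, W. et al., 2013",25,"30",MNI,,,,DF,"word pairs","TBF > TBR (neutral words)"
"Yang, W. et al., 2016",32,"30",MNI,,,,DF,"word pairs","TBF > TBR"
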