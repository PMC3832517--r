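group,stimulus_id,ors1,msr1,se1,ors2,msr2,se2,t,sig,df,d
heterosexual,pleasure,1590,0.10,0.06,1145,-0.16,0.06,3.06,**,1375,0.17
heterosexual,marvelous,1567,0.02,0.06,1125,-0.23,0.06,2.95,**,1375,0.16
heterosexual,wonderful,1527,-0.10,0.06,1103,-0.30,0.06,2.36,*,1374,0.13
heterosexual,beautiful,1658,0.32,0.06,1261,0.20,0.05,1.54,,1374,0.08
heterosexual,terrible,1654,0.31,0.06,1269,0.22,0.05,1.15,,1374,0.06
heterosexual,awful,1577,0.07,0.06,1215,0.07,0.06,0.00,,1372,0.00
heterosexual,joyful,1601,0.13,0.06,1242,0.14,0.06,-0.12,,1375,0.01
heterosexual,humiliate,1510,-0.15,0.06,1155,-0.13,0.06,-0.24,,1373,0.01
heterosexual,horrible,1638,0.26,0.06,1291,0.29,0.05,-0.38,,1374,0.02
heterosexual,agony,1544,-0.05,0.06,1192,0.00,0.06,-0.59,,1374,0.03
heterosexual,glorious,1562,0.00,0.06,1235,0.12,0.06,-1.41,,1375,0.08
heterosexual,lovely,1389,-0.51,0.05,1080,-0.39,0.06,-1.54,,1372,0.08
heterosexual,painful,1584,0.08,0.06,1271,0.24,0.05,-2.05,*,1374,0.11
heterosexual,nasty,1454,-0.32,0.05,1155,-0.12,0.06,-2.56,*,1374,0.14
heterosexual,tragic,1502,-0.18,0.05,1218,0.07,0.06,-3.20,**,1375,0.17
bisexual,humiliate,121,0.32,0.20,97,-0.29,0.20,2.16,*,103,0.43
bisexual,horrible,131,0.75,0.22,108,0.13,0.19,2.13,*,103,0.42
bisexual,tragic,123,0.40,0.20,106,0.05,0.19,1.27,,103,0.25
bisexual,awful,114,0.05,0.19,102,-0.10,0.19,0.56,,103,0.11
bisexual,lovely,103,-0.36,0.19,94,-0.41,0.20,0.18,,103,0.04
bisexual,painful,117,0.17,0.20,109,0.16,0.19,0.04,,103,0.01
bisexual,beautiful,120,0.28,0.20,112,0.27,0.19,0.04,,103,0.01
bisexual,glorious,112,-0.03,0.19,104,-0.03,0.19,0.00,,103,0.00
bisexual,terrible,112,-0.03,0.19,104,-0.03,0.19,0.00,,103,0.00
bisexual,pleasure,110,-0.10,0.19,104,-0.02,0.19,-0.30,,103,0.06
bisexual,agony,110,-0.10,0.19,108,0.13,0.19,-0.86,,103,0.17
bisexual,marvelous,109,-0.14,0.19,108,0.12,0.19,-0.97,,103,0.19
bisexual,wonderful,101,-0.43,0.19,101,-0.13,0.19,-1.12,,104,0.22
bisexual,nasty,100,-0.47,0.19,102,-0.10,0.19,-1.38,,103,0.27
bisexual,joyful,108,-0.17,0.19,109,0.23,0.20,-1.45,,102,0.29
gay,glorious,97,0.31,0.21,87,-0.30,0.21,2.05,*,91,0.43
gay,painful,98,0.36,0.21,94,0.00,0.21,1.21,,91,0.25
gay,lovely,81,-0.37,0.21,80,-0.61,0.21,0.81,,91,0.17
gay,nasty,89,-0.02,0.21,88,-0.25,0.21,0.77,,91,0.16
gay,terrible,101,0.49,0.21,103,0.38,0.21,0.37,,91,0.08
gay,wonderful,81,-0.37,0.21,84,-0.42,0.21,0.17,,91,0.04
gay,joyful,90,0.02,0.21,94,0.00,0.21,0.07,,91,0.01
gay,awful,90,0.02,0.21,95,0.04,0.21,-0.07,,91,0.01
gay,marvelous,94,0.19,0.21,102,0.34,0.21,-0.51,,91,0.11
gay,humiliate,85,-0.11,0.21,95,0.04,0.21,-0.51,,90,0.11
gay,horrible,100,0.45,0.21,109,0.66,0.22,-0.69,,91,0.14
gay,tragic,81,-0.37,0.21,91,-0.13,0.21,-0.81,,91,0.17
gay,pleasure,83,-0.28,0.21,94,0.00,0.21,-0.94,,91,0.20
gay,agony,82,-0.32,0.21,94,0.00,0.21,-1.08,,91,0.23
gay,beautiful,90,0.02,0.21,102,0.34,0.21,-1.08,,91,0.23
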