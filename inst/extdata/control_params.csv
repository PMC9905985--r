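"scenario","objective","kp1","kp2","kp3","kd1","kd2","kd3","t_pred","seed","generations","population"
"no_passive",0.0750750229484998,300,148.725890935506,66.793631248419,33.4073749649155,16.5818264044079,3.45813818827033,0.015,101,50,30
"A",0.924679214429675,300,138.011815836074,19.6433310276442,46.4608255293737,23.0063523102979,17.4736743353744,0.013,102,50,30
"B",1.38428794593541,300,150.473841066782,15.0070852177777,43.6673585939899,23.0063523102979,17.4736743353744,0.013,103,30,20
"C",1.77782848105563,290.880520905369,159.111950535453,0,50,14.2839673203565,18.1465102623626,0.013,104,30,20
"D",2.55448153276905,299.253896074354,161.047202825919,0,50,22.1480475471266,17.4736743353744,0.013,105,30,20
"E",2.78551493738376,300,210.964823875718,19.6433310276442,50,34.6214267280479,15.9716836814717,0.013,106,30,20
"F",3.85659055062896,300,232.490713746307,0,43.9362889349445,19.7521910377145,17.5030582340904,0.013,107,30,20
"G",6.40200833720198,297.25501705878,297.187821306927,0,50,32.4546046698262,16.3476260460271,0.013,108,30,20
"H",7.77593344424726,300,300,174.002788506102,1.4279296319913,12.5817110992362,16.6774808162729,0.04,109,30,20
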