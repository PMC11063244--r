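gene_id	interpro_accs
AN0016	IPR000873;IPR001242;IPR006162;IPR009081;IPR010071;IPR020806;IPR020845;IPR023213;IPR036736;IPR042099;IPR045851
AN0029	IPR011701;IPR020846;IPR036259
AN2959	IPR011701;IPR020846;IPR036259
AN3225	IPR002403;IPR001128;IPR036396;IPR017972
AN4643	IPR001128;IPR002401;IPR036396;IPR017972
AN5310	IPR002938;IPR036188
AN5553	IPR001128;IPR002401;IPR036396;IPR017972
AN6450	IPR002347;IPR020904;IPR036291
AN7154	IPR008030;IPR036291
AN7359	IPR001128;IPR002401;IPR036396;IPR017972
AN7772	IPR001128;IPR002401;IPR017972;IPR036396
AN7969	IPR001128;IPR002401;IPR036396;IPR017972
AN7972	IPR011701;IPR020846;IPR036259
AN8354	IPR008030;IPR036291;IPR045312
AN8952	IPR001128;IPR002401;IPR036396
AN8970	IPR016040;IPR036291
AN9005	IPR001227;IPR009081;IPR011032;IPR013217;IPR013968;IPR014030;IPR014031;IPR014043;IPR016035;IPR016036;IPR016039;IPR018201;IPR020807;IPR020841;IPR020843;IPR029063;IPR032821;IPR036291;IPR036736;IPR042104;IPR049551;IPR049552
AN9044	IPR001155;IPR013785;IPR044152
AN9161	IPR002938;IPR036188
AN9181	IPR008030;IPR036291;IPR045312
AN10259	IPR001128;IPR002401;IPR036396;IPR017972
AN11681	
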