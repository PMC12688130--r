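species,condition,n_cycles,n_id,avg_length_days,dispersion,site,dispersion_is_se
bonobo,C,6,1,15.3,NA,Yerkes,FALSE
bonobo,C,9,4,11.5,2.7,Planckendael,TRUE
bonobo,C,23,8,16.0,6.8,Cologne and 3 sites,FALSE
bonobo,C,57,4,13.4,0.7,Apenheul,TRUE
bonobo,W,70,13,10.6,6.8,Luikotale,FALSE
bonobo,W,9,3,14.6,7.4,Wamba,FALSE
bonobo,W,9,NA,12.9,9.3,Wamba,FALSE
bonobo,W,36,9,14.0,11.2,Wamba,FALSE
chimpanzee,C,53,13,11.9,4.4,Norman OK,FALSE
chimpanzee,C,158,10,10.4,NA,Yerkes,FALSE
chimpanzee,W,41,46,12.7,NA,Gombe and 2 sites,FALSE
chimpanzee,W,33,12,10.9,3.2,Tai,FALSE
chimpanzee,W,27,28,12.5,NA,Mahale,FALSE
chimpanzee,W,37,5,10.9,NA,Mahale,FALSE
chimpanzee,W,37,6,9.6,NA,Gombe,FALSE
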