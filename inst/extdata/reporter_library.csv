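enhancer,construct,intact_sites,fold_enhancement,source
Scl+19,mut2_gata_only,GATA,40,placeholder
Scl+19,mut1_ets_only,ETS,60,placeholder
Scl+19,wt,GATA;ETS,820.51,measured
Gata2-3,gata_only,GATA,15,placeholder
Gata2-3,ets_only,ETS,25,placeholder
Gata2-3,dEbox,GATA;ETS,150,placeholder
Gata2-3,wt,GATA;ETS;EBOX,500,placeholder
Fli1+12,pgata_only,pGATA,5,placeholder
Fli1+12,ets_only,ETS,8,placeholder
Fli1+12,pgata_ets,pGATA;ETS,20,measured
Fli1+12,wt,pGATA;ETS;EBOX;sGATA,60,measured
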