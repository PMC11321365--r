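wavelength_nm,reflectance
360,0.0702515125978499
370,0.0703509675442247
380,0.0704897240031645
390,0.0706832883958005
400,0.070953262197311
410,0.0713297159460941
420,0.0718544673674761
430,0.0725855884761727
440,0.0736035646653696
450,0.0750196381932137
460,0.0769869695088
470,0.0797152956480219
480,0.0834896574715687
490,0.0886933199853355
500,0.0958338967496584
510,0.105569404883175
520,0.118726876846498
530,0.136299757905294
540,0.159402191516588
550,0.189151828660686
560,0.226456395494534
570,0.271706066027496
580,0.324432723425637
590,0.383072345153264
600,0.445
610,0.506927654846736
620,0.565567276574363
630,0.618293933972504
640,0.663543604505466
650,0.700848171339314
660,0.730597808483412
670,0.753700242094706
680,0.771273123153502
690,0.784430595116825
700,0.794166103250342
710,0.801306680014664
720,0.806510342528431
730,0.810284704351978
740,0.8130130304912
750,0.814980361806787
760,0.81639643533463
770,0.817414411523827
780,0.818145532632524
790,0.818670284053906
800,0.819046737802689
810,0.819316711604199
820,0.819510275996835
830,0.819649032455775
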