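# Synthetic haemoglobin-like absorption curve (arbitrary units per concentration x path).
# Implementer-built fixture: Gaussian peaks at 415 nm and 540 nm on a flat baseline with
# a trough near 650-700 nm. NOT literature haemoglobin data; shaped only to place the
# absorption maxima under the narrow blue/green illumination bands.
wavelength_nm,mu
380,0.21365
385,0.3676
390,0.60054
395,0.90988
400,1.26434
405,1.6029
410,1.84946
415,1.94
420,1.84946
425,1.6029
430,1.26435
435,0.90991
440,0.60062
445,0.36779
450,0.2141
455,0.12451
460,0.07864
465,0.05906
470,0.05442
475,0.05919
480,0.07212
485,0.09458
490,0.12947
495,0.18012
500,0.24939
505,0.33845
510,0.44578
515,0.56622
520,0.69092
525,0.80801
530,0.90432
535,0.96782
540,0.99
545,0.96782
550,0.90432
555,0.80801
560,0.69092
565,0.56622
570,0.44578
575,0.33845
580,0.24938
585,0.18012
590,0.12944
595,0.09445
600,0.07162
605,0.05752
610,0.04925
615,0.04466
620,0.04224
625,0.04103
630,0.04045
635,0.04019
640,0.04007
645,0.04003
650,0.04001
655,0.04
660,0.04
665,0.04
670,0.04
675,0.04
680,0.04
685,0.04
690,0.04
695,0.04
700,0.04
705,0.04
710,0.04
715,0.04
720,0.04
725,0.04
730,0.04
735,0.04
740,0.04
745,0.04
750,0.04
755,0.04
760,0.04
765,0.04
770,0.04
775,0.04
780,0.04
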