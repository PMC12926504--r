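wavelength_nm,value
550,0.000045
560,0.000060
570,0.000075
580,0.000090
590,0.00013
600,0.00023
610,0.00027
620,0.00028
630,0.00030
640,0.00032
650,0.00034
660,0.00040
670,0.00044
680,0.00050
690,0.00055
700,0.00060
710,0.00100
720,0.00140
730,0.00190
740,0.00240
750,0.00260
760,0.00270
770,0.00250
780,0.00230
790,0.00215
800,0.00200
810,0.00220
820,0.00260
830,0.00300
840,0.00360
850,0.00430
860,0.00480
870,0.00530
880,0.00580
890,0.00630
900,0.00680
910,0.00730
920,0.00780
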