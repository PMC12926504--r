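wavelength_nm,hbo2,hb
550,43016,53412
560,32613,53788
570,44940,48383
580,50104,37020
590,20862,28324
600,3200,14677
610,1506,9443
620,942,6510
630,610,5149
640,442,4345
650,368,3750
660,320,3227
670,294,2795
680,278,2407
690,276,2051
700,290,1794
710,314,1540
720,334,1244
730,390,1103
740,446,1115
750,518,1405
760,586,1548
770,650,1311
780,710,1076
790,766,903
800,816,762
810,864,718
820,916,693
830,974,690
840,1022,688
850,1058,692
860,1086,712
870,1110,730
880,1128,742
890,1160,762
900,1198,798
910,1220,822
920,1240,848
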