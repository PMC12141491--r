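"wavelength_nm","absorbance_rel"
640,0.26605
642,0.242758
644,0.220124
646,0.199886
648,0.184012
650,0.174709
652,0.174379
654,0.185512
656,0.21047
658,0.251177
660,0.308698
662,0.382789
664,0.471491
666,0.570882
668,0.675103
670,0.776722
672,0.867454
674,0.939146
676,0.984884
678,1
680,0.982781
682,0.934721
684,0.86026
686,0.766077
688,0.660074
690,0.550273
692,0.443835
694,0.346353
696,0.261497
698,0.191013
700,0.134991
702,0.092298
704,0.061056
706,0.039076
708,0.024195
710,0.014494
712,0.0084
714,0.00471
716,0.002555
718,0.001341
720,0.000681
722,0.000335
724,0.000159
726,7.3e-05
728,3.3e-05
730,1.4e-05
732,6e-06
734,2e-06
736,1e-06
738,0
740,0
742,0
744,0
746,0
748,0
750,0
752,0
754,0
756,0
758,0
760,0
762,0
764,0
766,0
768,0
770,0
772,0
774,0
776,0
778,0
780,0
782,0
784,0
786,0
788,0
790,0
792,0
794,0
796,0
798,0
800,0
802,0
804,0
806,0
808,0
810,0
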