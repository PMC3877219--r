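# Primary-bond shift perturbation grid, carboxylate acceptors
# (N-methylacetamide/acetate-like scan). Columns: r (A), angle (deg, H...O=C),
# value (ppm). Bilinear interpolation between nodes; synthetic values.
r	angle	value
1.4	90	3.90653681516876
1.6	90	2.51595198927082
1.8	90	1.62036471478699
2	90	1.04357389176082
2.2	90	0.672099594385442
2.4	90	0.432856617379431
2.6	90	0.278775426699203
2.8	90	0.179541528097281
3	90	0.115631283191571
3.2	90	0.0744707577919505
3.4	90	0.0479618803236773
3.6	90	0.030889197752079
3.8	90	0.0198937683703784
4	90	0.0128123113831155
1.4	100	4.14212981229495
1.6	100	2.66768245997222
1.8	100	1.71808466410678
2	100	1.10650909818916
2.2	100	0.712632159493682
2.4	100	0.458961065549062
2.6	100	0.295587642072723
2.8	100	0.190369207116921
3	100	0.122604702836017
3.2	100	0.0789618940224704
3.4	100	0.0508543356281782
3.6	100	0.0327520443145327
3.8	100	0.0210935094034881
4	100	0.0135849883043061
1.4	110	4.82049281123778
1.6	110	3.10457293800659
1.8	110	1.99945804398534
2	110	1.28772380275421
2.2	110	0.829341029269397
2.4	110	0.534125828348071
2.6	110	0.34399648689736
2.8	110	0.22154626628655
3	110	0.142683864443522
3.2	110	0.091893605402518
3.4	110	0.0591828287438641
3.6	110	0.0381158972137747
3.8	110	0.0245480260279323
4	110	0.0158098228276853
1.4	120	5.85980522275313
1.6	120	3.77392798390623
1.8	120	2.43054707218048
2	120	1.56536083764123
2.2	120	1.00814939157816
2.4	120	0.649284926069147
2.6	120	0.418163140048805
2.8	120	0.269312292145921
3	120	0.173446924787356
3.2	120	0.111706136687926
3.4	120	0.0719428204855159
3.6	120	0.0463337966281185
3.8	120	0.0298406525555676
4	120	0.0192184670746732
1.4	130	7.13471063139469
1.6	130	4.59501350050727
1.8	130	2.95935604969542
2	130	1.90593307895658
2.2	130	1.22749031899517
2.4	130	0.790548471959852
2.6	130	0.509142008573769
2.8	130	0.327905997024933
3	130	0.211183404775637
3.2	130	0.136009804203853
3.4	130	0.0875952675316686
3.6	130	0.0564145426049161
3.8	130	0.0363330201163126
4	130	0.0233997882428517
1.4	140	8.49143662928034
1.6	140	5.46879445657601
1.8	140	3.52210280945253
2	140	2.26836248808669
2.2	140	1.4609080585466
2.4	140	0.940877997557872
2.6	140	0.605959698223044
2.8	140	0.39026011536419
3	140	0.251341727990647
3.2	140	0.161873226963948
3.4	140	0.10425225376304
3.6	140	0.0671422484034
3.8	140	0.043242053365201
4	140	0.0278494572896103
1.4	150	9.76634203792189
1.6	150	6.28987997317705
1.8	150	4.05091178696747
2	150	2.60893472940204
2.2	150	1.6802489859636
2.4	150	1.08214154344858
2.6	150	0.696938566748009
2.8	150	0.448853820243202
3	150	0.289078207978927
3.2	150	0.186176894479876
3.4	150	0.119904700809193
3.6	150	0.0772229943801976
3.8	150	0.049734420925946
4	150	0.0320307784577888
1.4	160	10.8056544494373
1.6	160	6.95923501907669
1.8	160	4.48200081516262
2	160	2.88657176428905
2.2	160	1.85905734827237
2.4	160	1.19730064116965
2.6	160	0.771105219899454
2.8	160	0.496619846102573
3	160	0.319841268322761
3.2	160	0.205989425765284
3.4	160	0.132664692550845
3.6	160	0.0854408937945414
3.8	160	0.0550270474535812
4	160	0.0354394227047767
1.4	170	11.4840174483801
1.6	170	7.39612549711106
1.8	170	4.76337419504117
2	170	3.06778646885411
2.2	170	1.97576621804809
2.4	170	1.27246540396866
2.6	170	0.819514064724091
2.8	170	0.527796905272202
3	170	0.339920429930267
3.2	170	0.218921137145332
3.4	170	0.140993185666531
3.6	170	0.0908047466937834
3.8	170	0.0584815640780255
4	170	0.0376642572281559
1.4	180	11.7196104455063
1.6	180	7.54785596781246
1.8	180	4.86109414436097
2	180	3.13072167528245
2.2	180	2.01629878315633
2.4	180	1.29856985213829
2.6	180	0.83632628009761
2.8	180	0.538624584291842
3	180	0.346893849574713
3.2	180	0.223412273375851
3.4	180	0.143885640971032
3.6	180	0.0926675932562371
3.8	180	0.0596813051111352
4	180	0.0384369341493465
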