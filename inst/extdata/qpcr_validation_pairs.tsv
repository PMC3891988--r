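# Platform validation set: 66 rice genes assayed in shoot vs root by both
# the 60-mer one-channel microarray and qRT-PCR (2^-ddCt, Actin reference).
# Columns: MSU locus id, microarray log2 ratio, qPCR log2 ratio.
gene_id	array_log2	qpcr_log2
Os07g29600	0.73	0.14
Os07g48180	-0.04	-0.7
Os08g15840	-0.99	-0.66
Os08g26880	1.42	1.19
Os08g03310	4.58	4.99
Os08g33660	3.93	2.8
Os09g35880	0.93	0.97
Os09g33670	-0.13	-0.12
Os09g36250	0.75	0.2
Os09g30400	-0.17	-0.48
Os09g32510	2.66	1.73
Os09g26400	-0.17	-0.53
Os09g29960	2.57	2.71
Os10g33940	-1.11	-0.32
Os12g13170	-0.08	0.66
Os12g31840	-0.45	-0.38
Os01g72330	2.53	2.42
Os01g70310	4.86	4.05
Os01g66420	0.02	-0.28
Os02g02290	0.14	0.11
Os01g59660	-1.41	-0.76
Os01g48130	0.31	-0.02
Os02g05510	-0.53	-0.09
Os02g35600	2.08	0.74
Os02g29550	0.42	1.23
Os02g55320	0.84	0.46
Os02g52340	2.78	2.13
Os02g50480	0.12	0.49
Os03g43800	-0.18	0.21
Os03g20550	-2.11	-2.45
Os03g61640	-0.64	0.3
Os03g60080	-4.04	-4.17
Os04g49450	-2.27	-2.01
Os04g57610	1.17	1.13
Os04g58020	0.1	-0.12
Os06g03580	-2.82	-2.41
Os05g46370	-0.55	-0.81
Os05g37170	-2.58	-1.44
Os06g24070	4.09	4.63
Os06g33810	0.27	-0.25
Os06g41390	-0.6	-0.02
Os03g55270	-0.73	-0.5
Os01g04800	-3.02	-2.99
Os01g04120	-3.41	-4.35
Os01g11550	2.09	3
Os07g48410	0.68	0.85
Os07g38030	1.77	1.44
Os07g49460	-1.54	-0.69
Os08g40900	-0.82	0.55
Os09g21180	1.06	0.23
Os10g42130	-0.03	-0.19
Os01g74410	-4.45	-3.84
Os01g55150	0.18	0.15
Os02g08440	-5.14	-2.75
Os02g43790	-4.02	-1.47
Os02g42380	4.84	4.24
Os02g54830	0.35	-0.04
Os02g47810	2.99	1.97
Os03g09170	-5.3	-3.76
Os03g08960	3.17	2.13
Os02g51280	0.05	0.4
Os03g17570	-1.86	-1.42
Os03g60560	-5.18	-6.27
Os05g04820	0.68	0.7
Os05g36290	-0.97	0
Os06g12230	0.89	0.29
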