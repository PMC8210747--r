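species	n	monomerSize	atPercent	abundance	intraKD
Characidium gomesi	2145	52	71.5	3.53e-03	15.43
Hopilas malabaricus	.	52	.	3.03917e-05	21.5
Hemiodus gracilis	116	52	66	0.000923	16.1
Piaractus mesopotamicus	6	52	67.4	0.000124	19.4
Myleus asterias	12	52	66.2	0.000155	18.2
Pygocentrus nattereri	63	52	65.5	0.000182849	18.6
Prochilodus lineatus	90	52	59.3	0.000287	14.4
Leporinus friderici	69	52	67.4	0.000196	14.5
Megaleporinus macrocephalus	187	52	67.6	0.000315	13.5
Brycon orbignyanus	63	52	64.6	0.000191	8.16
Astyanax mexicanus	33	52	68.2	0.000179	13.2
Astyanax paranae	65	52	67.7	0.000137	11.3
Moenkhausia sanctaefilomenae	104	52	67.9	0.00074	9.48
Distichodus sexfasciatus	.	.	.	0	0.00
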