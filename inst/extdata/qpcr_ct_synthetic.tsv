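sample	target	replicate	Ct
muscle1	sat	1	24.10
muscle1	sat	2	24.05
muscle1	sat	3	24.21
muscle1	hprt1	1	24.02
muscle1	hprt1	2	23.95
muscle1	hprt1	3	24.06
muscle2	sat	1	24.40
muscle2	sat	2	24.32
muscle2	sat	3	24.48
muscle2	hprt1	1	24.11
muscle2	hprt1	2	24.02
muscle2	hprt1	3	24.15
ovary1	sat	1	28.05
ovary1	sat	2	27.96
ovary1	sat	3	28.13
ovary1	hprt1	1	24.03
ovary1	hprt1	2	23.98
ovary1	hprt1	3	24.08
ovary2	sat	1	27.80
ovary2	sat	2	27.92
ovary2	sat	3	27.71
ovary2	hprt1	1	23.90
ovary2	hprt1	2	23.99
ovary2	hprt1	3	23.94
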