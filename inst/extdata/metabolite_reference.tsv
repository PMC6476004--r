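metabolite	peaks	base_conc	polyp_vs_control	crc_vs_control	crc_vs_polyp
Lipid	0.86:bra:1:1	1.2	up:1.07	down:1.19	down:1.15
Leucine	0.96:t:0.5:1;1.70:m:0.35:0;3.73:m:0.15:0	0.25	up:1.08	down:1.23	down:1.16
Isoleucine	0.92:t:0.45:1;1.02:d:0.35:1;3.73:m:0.2:0	0.15	none:1.01	up:1.28	none:1.01
Valine	0.98:d:0.45:0;1.05:d:0.35:1;3.61:d:0.2:0	0.25	down:1.09	down:1.17	down:1.12
3-Hydroxybutyrate	1.20:d:0.4:1;2.28:q:0.2:0;2.40:q:0.2:0;4.15:m:0.2:0	0.2	none:1.01	up:1.59	none:1.08
Lactate	1.33:d:0.6:1;4.12:q:0.4:0	0.5	up:1.51	up:1.48	none:1.06
Alanine	1.48:d:0.6:1;3.78:q:0.4:0	0.3	down:1.12	down:1.17	down:1.18
Acetate	1.92:s:1:1	0.15	up:1.21	up:1.18	none:1.02
Glutamate	2.08:m:0.5:1;2.34:m:0.5:0	0.25	up:1.41	up:1.20	up:1.18
Glutamine	2.13:m:0.5:0;2.45:m:0.5:1	0.35	down:1.19	down:1.18	down:1.19
Succinate	2.37:s:1:1	0.12	down:1.12	down:1.23	none:1.13
Citrate	2.54:d:0.5:1;2.66:d:0.5:1	0.15	none:1.01	down:1.21	down:1.17
Aspartate	2.87:m:0.5:1;2.94:m:0.5:1	0.15	down:1.40	down:1.62	none:1.09
Choline	3.20:s:1:1	0.2	up:1.23	up:1.20	none:1.02
Proline	3.36:m:1:1	0.2	none:1.03	down:1.20	down:1.26
Glycine	3.57:s:1:1	0.25	up:1.19	up:1.46	none:1.04
Glucose	3.24:q:0.2:1;3.48:t:0.2:1;3.54:t:0.15:0;3.71:t:0.15:0;3.83:t:0.15:0;3.90:q:0.15:0	1.2	down:1.25	up:1.53	up:1.31
Serine	3.84:m:0.5:0;3.96:m:0.5:1	0.2	up:1.32	up:1.18	up:1.23
Tyrosine	6.90:d:0.5:1;7.20:d:0.5:1	0.15	none:1.01	down:1.19	down:1.22
N-Acetyl-glycoprotein	2.03:s:1:1	0.4	down:1.27	none:1.01	up:1.21
PUFA	2.795:bra:1:1	0.5	up:1.18	none:1.04	down:1.37
Glycerol	3.61:m:0.5:0;3.65:m:0.5:1	0.25	down:1.32	none:1.07	none:1.05
Lysine	1.45:m:0.25:0;1.71:m:0.25:0;1.89:m:0.15:0;3.02:t:0.2:1;3.75:t:0.15:0	0.25	none:1.02	none:1.03	up:1.26
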