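# X-ray atomic scattering factors, 4-Gaussian + constant parameterization
# (International Tables for Crystallography Vol. C, Table 6.1.1.4).
# f(s) = sum_i a_i * exp(-b_i * s^2) + c,  s = sin(theta)/lambda = 1/(2d)  [1/A]
# a_i, c in electrons; b_i in A^2.  f(0) = sum(a_i) + c = Z.
element	a1	a2	a3	a4	b1	b2	b3	b4	c
H	0.493002	0.322912	0.140191	0.040810	10.5109	26.1257	3.14236	57.7997	0.003038
C	2.310000	1.020000	1.588600	0.865000	20.8439	10.2075	0.56870	51.6512	0.215600
N	12.212600	3.132200	2.012500	1.166300	0.00570	9.89330	28.9975	0.58260	-11.529000
O	3.048500	2.286800	1.546300	0.867000	13.2771	5.70110	0.32390	32.9089	0.250800
S	6.905300	5.203400	1.437900	1.586300	1.46790	22.2151	0.25360	56.1720	0.866900
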