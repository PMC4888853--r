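case	sex	age_onset	age_takeoff	age_phv
1.II.1	M	15.2	14.76	15.6
2.II.1	M	15.6	15.81	16.2
3.III.2	M	15.5	15.6	17
4.III.1	M	16.5	16.11	17.3
5.II.1	M	16.10	15.59	16.2
6.II.1	M	15.21	15.6	16.18
7.III.5	M	16.5	16.5	17.3
8.III.2	F	13.94	13.94	14.68
9.II.4	M	15.21	15.5	16.1
10.II.1	M	15.4	15.91	16.4
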