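sample_id	group	q0	q1	q2	q3	q4
0A	pre	57	19.264	10.856	8.280	7.172
2A	pre	59	8.227	3.185	2.487	2.257
4A	pre	59	7.357	4.389	3.644	3.307
6A	pre	57	9.131	5.772	4.910	4.534
10A	pre	53	11.532	7.756	6.406	5.715
12A	pre	51	3.063	2.078	1.867	1.770
14A	pre	54	10.756	6.167	5.000	4.487
16A	pre	51	1.514	1.178	1.133	1.117
0B	post	61	28.335	20.045	16.248	14.188
2B	post	61	11.679	4.406	3.214	2.833
4B	post	56	11.432	6.827	5.530	4.938
6B	post	48	5.863	3.872	3.389	3.165
10B	post	54	11.055	7.525	6.671	6.308
12B	post	46	2.851	2.187	2.056	1.986
14B	post	57	6.996	4.408	3.651	3.303
16B	post	55	7.533	3.871	3.114	2.811
H1	healthy	46	22.130	14.242	11.362	10.030
H2A	healthy	42	15.721	10.483	8.897	8.149
H2B	healthy	44	18.051	10.976	8.642	7.584
H3	healthy	50	20.789	14.849	12.792	11.775
H5	healthy	42	20.522	14.271	11.929	10.777
H6	healthy	52	22.699	14.082	10.243	8.422
H7	healthy	44	19.175	11.909	9.591	8.564
H8	healthy	46	18.674	11.846	9.465	8.314
H10	healthy	48	15.379	8.988	7.048	6.189
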