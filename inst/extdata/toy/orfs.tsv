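orf_id	scaffold_id	start	end	strand	length_aa
o01	S01	100	463	+	120
o02	S01	600	750	+	49
o03	S01	1000	1903	-	300
o04	S02	50	203	+	50
o05	S02	500	743	-	80
o06	S03	0	603	+	200
o07	S03	900	1353	+	150
o08	S04	10	193	+	60
o09	S05	0	150	+	49
o10	S07	2000	3503	+	500
o11	S07	4000	4213	-	70
o12	S08	100	373	+	90
o13	S09	5000	5333	+	110
o14	S09	6000	6147	-	48
o15	S11	700	928	+	75
o16	S12	0	303	+	100
o17	S12	1000	1393	+	130
o18	S12	2000	2168	-	55
o19	S12	3000	3150	+	49
o20	S12	4000	4195	+	64
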