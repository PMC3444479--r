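gene	start	end	strand	coding
RNR1	648	1601	+	FALSE
RNR2	1671	3229	+	FALSE
ND1	3307	4262	+	TRUE
ND2	4470	5511	+	TRUE
COX1	5904	7445	+	TRUE
COX2	7586	8269	+	TRUE
ATP8	8366	8572	+	TRUE
ATP6	8527	9207	+	TRUE
COX3	9207	9990	+	TRUE
ND3	10059	10404	+	TRUE
ND4L	10470	10766	+	TRUE
ND4	10760	12137	+	TRUE
ND5	12337	14148	+	TRUE
ND6	14149	14673	-	TRUE
CYTB	14747	15887	+	TRUE
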