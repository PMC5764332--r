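# Fifty-five-segment systemic arterial tree (Stergiopulos/Olufsen-type geometry).
# Nominal subject height 175 cm. Lengths and radii in cm. Empty parent_id marks the root
# (ascending aorta); RT/CT are present only on terminal segments and parametrize the
# three-element Windkessel outflow (R1 = 0.2 RT, R2 = 0.8 RT).
# RT_1e4_cgs: terminal resistance in units of 1e4 g s^-1 cm^-4.
# CT_1e-6_cgs: terminal compliance in units of 1e-6 cm^4 s^2 g^-1. The source table prints
# the same unit string for RT and CT; CT is interpreted as the compliance entering the
# Windkessel R2*CT time constant, in CGS after the 1e-6 scale.
id,name,length_cm,r_in_cm,r_out_cm,parent_id,RT_1e4_cgs,CT_1e-6_cgs
1,Ascending aorta,4,1.525,1.42,,,
2,Aortic arch A,3,1.42,1.342,1,,
3,Brachiocephalic,4,0.95,0.7,1,,
4,R subclavian,4,0.425,0.407,3,,
5,R com. carotid,17,0.525,0.4,3,,
6,R vertebral,14,0.2,0.2,4,4.79,1.32
7,R brachial,40,0.407,0.25,4,,
8,R radial,22,0.175,0.175,7,4.41,1.09
9,R ulnar A,22,0.175,0.175,7,,
10,Aortic arch B,4,1.342,1.246,2,,
11,L com. carotid,17,0.525,0.4,2,,
12,Thoracic aorta A,6,1.246,1.124,10,,
13,Thoracic aorta B,11,1.124,0.924,12,,
14,Intercostals,7,0.63,0.5,12,1.33,5.43
15,L subclavian,4,0.425,0.407,10,,
16,L vertebral,14,0.2,0.2,15,4.79,1.32
17,L brachial,40,0.407,0.25,15,,
18,L ulnar A,22,0.175,0.175,17,,
19,L radial,22,0.175,0.175,17,4.41,1.09
20,Celiac axis,2,0.35,0.3,13,,
21,Hepatic A,2,0.3,0.25,20,,
22,Hepatic B,7,0.275,0.25,20,3.86,2.38
23,Gastric,6,0.175,0.15,21,5,1.29
24,Splenic,6,0.2,0.2,21,2.15,5.47
25,Abdominal aorta A,5,0.924,0.838,13,,
26,Superior mesenteric,5,0.4,0.35,25,0.92,23.91
27,Abdominal aorta B,2,0.838,0.814,25,,
28,R renal,3,0.275,0.275,27,1.03,13.92
29,Abdominal aorta C,2,0.814,0.792,27,,
30,L renal,3,0.275,0.275,29,1.03,13.92
31,Abdominal aorta D,13,0.792,0.627,29,,
32,Inferior mesenteric,4,0.2,0.175,31,6.84,0.85
33,Abdominal aorta E,8,0.627,0.55,31,,
34,R external iliac,6,0.4,0.37,33,,
35,R femoral A,15,0.37,0.314,34,,
36,R internal iliac,5,0.2,0.2,34,6.4,0.75
37,R deep femoral,11,0.2,0.2,35,4.65,1.49
38,R femoral B,44,0.314,0.2,35,,
39,R ext. carotid,16,0.275,0.2,5,16.25,0.19
40,R int. carotid,16,0.275,0.2,5,16.25,0.19
41,R post. tibial,32,0.125,0.125,38,5.47,0.91
42,R ant. tibial,32,0.125,0.125,38,4.51,1.23
43,R interosseous,7,0.1,0.1,9,8.68,0.33
44,R ulnar B,17,0.2,0.2,9,6.32,1.08
45,L ulnar B,17,0.2,0.2,18,6.32,1.08
46,L interosseous,7,0.1,0.1,18,8.68,0.33
47,L external iliac,6,0.4,0.37,33,,
48,L femoral A,15,0.37,0.314,47,,
49,L internal iliac,5,0.2,0.2,47,6.4,0.75
50,L deep femoral,11,0.2,0.2,48,4.65,1.49
51,L femoral B,44,0.314,0.2,48,,
52,L ext. carotid,16,0.275,0.2,11,16.25,0.19
53,L int. carotid,16,0.275,0.2,11,16.25,0.19
54,L post. tibial,32,0.125,0.125,51,5.47,0.91
55,L ant. tibial,32,0.125,0.125,51,4.51,1.23
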