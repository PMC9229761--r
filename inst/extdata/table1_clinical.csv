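subject_id,age,sex,tumor_side,tumor_location,who_grade,idh_status,radiation,chemotherapy,years_since_surgery,years_since_last_treatment,impaired
1,38,M,R,FC,II,mutant,Y,Y,6.43,4.75,no
2,38,M,L,FC,III,mutant,Y,Y,1.95,1.73,no
3,42,M,R,PC,III,mutant,Y,Y,6.00,4.42,no
4,39,M,L,FC,III,mutant,Y,Y,5.07,3.81,yes
5,50,F,L,FC,III,unknown,Y,Y,8.88,6.68,no
6,46,F,R,FC,IV,mutant,Y,Y,7.18,5.98,no
7,31,M,R,FPC,II,mutant,Y,Y,3.13,1.69,yes
8,32,M,R,TC,III,mutant,Y,Y,5.00,3.84,yes
9,41,M,R,FC,III,mutant,Y,Y,7.42,5.94,no
10,45,M,L,FC,III,mutant,Y,Y,3.89,2.77,no
11,62,M,R,FC,III,mutant,Y,Y,5.15,4.98,yes
12,57,M,L,FC,IV,mutant,Y,Y,9.00,7.45,yes
13,42,F,L,OC,IV,wild-type,Y,Y,8.26,6.40,yes
14,61,F,R,FC,III,mutant,Y,Y,2.36,1.23,yes
15,22,M,R,FTC,III,mutant,Y,Y,3.86,2.54,no
16,29,M,L,TC,II,mutant,N,N,4.49,4.49,no
17,70,M,R,FC,IV,wild-type,Y,Y,4.57,2.42,yes
18,48,M,R,PC,IV,mutant,Y,Y,10.99,8.17,no
19,45,F,L,PC,III,unknown,Y,Y,14.67,12.37,no
20,46,M,L,TC,II,mutant,Y,Y,6.73,5.43,yes
21,52,F,R,FC,II,mutant,Y,Y,2.51,0.70,yes
22,28,F,L,TC,II,mutant,Y,Y,2.91,1.35,yes
23,38,M,L,TC,II,mutant,Y,Y,5.83,0.60,yes
24,60,F,L,FC,III,unknown,Y,Y,22.39,21.63,no
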