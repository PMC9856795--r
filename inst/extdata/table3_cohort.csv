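patient_id,age_at_surgery,etiology,histology,engel_outcome,followup_years
1,1.3,HME,FCD Ic,IA,12.6
2,14.8,Rasmussen,Inflammatory infiltrate,IV,10.1
3,4.7,Perinatal ischemic injury,Gliosis,IA,4.8
4,17.7,Rasmussen,Gliosis,IA,7.6
5,2.9,HME,FCD IIa,IA,5.7
6,0.2,HME,FCD IIa,IA,5.8
7,4.5,Ischemic injury,Gliosis,IA,7.3
8,16.8,Vascular congenital abnormality,Gliosis,II,5.7
9,17.0,Perinatal ischemic injury,Gliosis,IV,7.5
10,7.0,Perinatal ischemic injury,Gliosis,IA,6.8
11,4.1,Hemispheric MCD,FCD Ic,III,4.4
12,0.2,HME,FCD IIa,IA,5.1
13,12.0,Post-infectious ischemic injury,Gliosis,IA,5.3
14,11.7,Perinatal ischemic injury,Gliosis,ID,4.9
15,7.0,Rasmussen,Inflammatory infiltrate,IA,4.8
16,8.8,Rasmussen,Inflammatory infiltrate,IA,2.3
17,17.9,Rasmussen,Inflammatory infiltrate,IA,2.9
18,0.7,Perinatal ischemic injury,Gliosis,IA,2.9
19,3.6,Rasmussen,Inflammatory infiltrate,ID,2.4
20,2.0,Hemispheric MCD,Neuronal heterotopia,IA,2.4
21,11.1,Rasmussen,Inflammatory infiltrate,IA,2.3
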