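# Cluster-scale reference FEP results: one ion fixed at the center of a cubic box of
# 512 TIP4P waters, NPT Metropolis Monte Carlo at 298.15 K, molecule-based truncation
# at 11.5 A for both ion-water and water-water interactions.  Charge leg: 10 double-wide
# windows, 10 M equilibration + 20 M averaging trials each; LJ leg: 5 double-wide
# windows, 20 M + 160 M trials each.  dgLJ = dG(0->LJ), dgQ = dG(LJ->LJ+q),
# mu = dG(0->LJ+q) = dgLJ + dgQ (uncorrected chemical potential).  se columns are
# statistical uncertainties.  Units kcal/mol; P in atm.  These runs are far beyond
# desk scale and enter the analysis layer as fixed inputs.
P	ion	dgLJ	dgLJse	dgQ	dgQse	mu	muse
1	K+	5.37	0.08	-76.3	0.2	-70.9	0.2
1	Rb+	6.25	0.09	-72.4	0.2	-66.2	0.2
1	Cs+	7.3	0.1	-67.6	0.2	-60.3	0.2
1	Br-	0.6	0.1	-57.9	0.2	-57.3	0.2
1	I-	1.1	0.2	-49.4	0.2	-48.3	0.3
1000	K+	6.66	0.09	-77.6	0.2	-70.9	0.2
1000	Rb+	7.8	0.1	-73.6	0.2	-65.8	0.2
1000	Cs+	8.6	0.1	-69.2	0.2	-60.6	0.2
1000	Br-	2.2	0.1	-57.1	0.3	-54.9	0.3
1000	I-	2.5	0.2	-49.1	0.3	-46.6	0.4
2000	K+	7.30	0.09	-78.4	0.2	-71.1	0.2
2000	Rb+	8.4	0.1	-75.1	0.2	-66.7	0.2
2000	Cs+	10.3	0.1	-69.8	0.2	-59.5	0.2
2000	Br-	3.1	0.1	-57.5	0.2	-54.4	0.2
2000	I-	4.4	0.2	-49.1	0.2	-44.7	0.3
3000	K+	8.8	0.1	-79.9	0.2	-71.1	0.2
3000	Rb+	9.4	0.1	-75.9	0.2	-66.5	0.2
3000	Cs+	11.4	0.1	-71.2	0.2	-59.8	0.2
3000	Br-	4.0	0.2	-58.0	0.2	-54.0	0.3
3000	I-	5.0	0.2	-49.2	0.2	-44.2	0.3
4000	K+	9.2	0.1	-81.2	0.2	-72.0	0.2
4000	Rb+	10.5	0.1	-76.7	0.2	-66.2	0.2
4000	Cs+	12.2	0.1	-72.1	0.2	-59.9	0.2
4000	Br-	4.6	0.2	-57.7	0.2	-53.1	0.3
4000	I-	6.5	0.2	-48.2	0.2	-41.7	0.3
6000	K+	10.4	0.1	-81.9	0.2	-71.5	0.2
6000	Rb+	12.0	0.1	-77.7	0.2	-65.7	0.2
6000	Cs+	14.7	0.1	-73.3	0.2	-58.6	0.2
6000	Br-	7.2	0.2	-57.1	0.2	-49.9	0.3
6000	I-	8.9	0.2	-48.7	0.2	-39.8	0.3
8000	K+	11.5	0.1	-83.4	0.2	-71.9	0.2
8000	Rb+	13.4	0.1	-79.2	0.1	-65.8	0.1
8000	Cs+	16.1	0.1	-73.9	0.2	-57.8	0.2
8000	Br-	9.2	0.2	-56.9	0.2	-47.7	0.3
8000	I-	12.1	0.3	-48.1	0.2	-36.0	0.4
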