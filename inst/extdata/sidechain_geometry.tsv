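# side-chain heavy-atom internal coordinates derived from idealized residue templates (v1)
res_name	atom	ref1	ref2	ref3	bond	angle	tors_kind	chi_idx	tors_value
ALA	CB	C	N	CA	1.5294	109.464	fixed	0	-119.999
ARG	CB	C	N	CA	1.5363	111.55	fixed	0	-123.561
ARG	CG	C	CA	CB	1.5371	114.536	chi	1	-121.355
ARG	CD	CA	CB	CG	1.5273	112.417	chi	2	0.0
ARG	NE	CB	CG	CD	1.4435	111.016	chi	3	0.0
ARG	CZ	CG	CD	NE	1.4058	123.005	chi	4	0.0
ARG	NH1	CD	NE	CZ	1.3906	120.996	fixed	0	179.986
ARG	NH2	CD	NE	CZ	1.3912	119.815	fixed	0	-0.012
ASN	CB	C	N	CA	1.5309	109.454	fixed	0	-119.996
ASN	CG	C	CA	CB	1.5066	109.484	chi	1	-120.031
ASN	ND2	CA	CB	CG	1.3476	120.012	chi	2	-179.926
ASN	OD1	CA	CB	CG	1.2133	119.974	chi	2	0.0
ASP	CB	C	N	CA	1.5301	109.48	fixed	0	-120.011
ASP	CG	C	CA	CB	1.5075	109.463	chi	1	-120.017
ASP	OD1	CA	CB	CG	1.208	119.959	chi	2	0.0
ASP	OD2	CA	CB	CG	1.3415	119.999	chi	2	-179.936
CYS	CB	C	N	CA	1.5285	109.496	fixed	0	-120.014
CYS	SG	C	CA	CB	1.8141	109.498	chi	1	-119.939
GLN	CB	C	N	CA	1.5288	109.459	fixed	0	-120.066
GLN	CG	C	CA	CB	1.5284	109.534	chi	1	-120.013
GLN	CD	CA	CB	CG	1.5066	109.543	chi	2	0.0
GLN	NE2	CB	CG	CD	1.3471	120.093	chi	3	-179.957
GLN	OE1	CB	CG	CD	1.2122	119.937	chi	3	0.0
GLU	CB	C	N	CA	1.5302	109.482	fixed	0	-119.956
GLU	CG	C	CA	CB	1.5306	109.402	chi	1	-119.984
GLU	CD	CA	CB	CG	1.5076	109.43	chi	2	0.0
GLU	OE1	CB	CG	CD	1.2084	120.003	chi	3	0.0
GLU	OE2	CB	CG	CD	1.3425	119.998	chi	3	-179.937
HIS	CB	C	N	CA	1.5337	111.125	fixed	0	-122.779
HIS	CG	C	CA	CB	1.51	112.979	chi	1	-123.474
HIS	CD2	CA	CB	CG	1.3376	129.928	chi	2	179.846
HIS	ND1	CA	CB	CG	1.3513	120.329	chi	2	0.0
HIS	NE2	CB	CG	CD2	1.3739	105.332	fixed	0	-179.864
HIS	CE1	CB	CG	ND1	1.3369	107.862	fixed	0	179.905
ILE	CB	C	N	CA	1.5288	109.43	fixed	0	-120.073
ILE	CG1	C	CA	CB	1.5294	109.547	chi	1	-120.035
ILE	CG2	C	CA	CB	1.5303	109.458	chi	1	119.993
ILE	CD1	CA	CB	CG1	1.5288	109.547	chi	2	0.0
LEU	CB	C	N	CA	1.5286	109.416	fixed	0	-119.973
LEU	CG	C	CA	CB	1.5303	109.495	chi	1	-119.939
LEU	CD1	CA	CB	CG	1.53	109.5	chi	2	0.0
LEU	CD2	CA	CB	CG	1.5285	109.501	chi	2	120.092
LYS	CB	C	N	CA	1.53	109.453	fixed	0	-119.967
LYS	CG	C	CA	CB	1.5307	109.418	chi	1	-119.977
LYS	CD	CA	CB	CG	1.5308	109.441	chi	2	0.0
LYS	CE	CB	CG	CD	1.5291	109.465	chi	3	0.0
LYS	NZ	CG	CD	CE	1.4694	109.5	chi	4	0.0
MET	CB	C	N	CA	1.5294	109.427	fixed	0	-120.037
MET	CG	C	CA	CB	1.5284	109.545	chi	1	-119.969
MET	SD	CA	CB	CG	1.8137	109.506	chi	2	0.0
MET	CE	CB	CG	SD	1.8135	100.034	chi	3	0.0
PHE	CB	C	N	CA	1.5289	109.474	fixed	0	-120.094
PHE	CG	C	CA	CB	1.5052	109.517	chi	1	-120.067
PHE	CD1	CA	CB	CG	1.3817	120.058	chi	2	0.0
PHE	CD2	CA	CB	CG	1.3832	120.005	chi	2	179.757
PHE	CE1	CB	CG	CD1	1.382	120.029	fixed	0	179.994
PHE	CE2	CB	CG	CD2	1.3819	119.977	fixed	0	179.839
PHE	CZ	CG	CD1	CE1	1.3806	120.047	fixed	0	-0.048
PRO	CB	C	N	CA	1.5434	104.722	fixed	0	-118.841
PRO	CG	C	CA	CB	1.5426	105.059	fixed	0	-142.62
PRO	CD	CA	CB	CG	1.5437	105.063	fixed	0	0.025
SER	CB	C	N	CA	1.5287	109.471	fixed	0	-120.02
SER	OG	C	CA	CB	1.4283	109.512	chi	1	-119.977
THR	CB	C	N	CA	1.529	109.412	fixed	0	-120.0
THR	CG2	C	CA	CB	1.5301	109.525	chi	1	120.045
THR	OG1	C	CA	CB	1.428	109.505	chi	1	-119.924
TRP	CB	C	N	CA	1.5286	109.523	fixed	0	-120.026
TRP	CG	C	CA	CB	1.5067	109.442	chi	1	-119.989
TRP	CD1	CA	CB	CG	1.3426	126.496	chi	2	0.0
TRP	CD2	CA	CB	CG	1.4639	126.512	chi	2	179.622
TRP	NE1	CB	CG	CD1	1.3686	109.932	fixed	0	179.944
TRP	CE2	CB	CG	CD2	1.4068	106.076	fixed	0	179.958
TRP	CE3	CB	CG	CD2	1.3961	134.047	fixed	0	0.784
TRP	CZ2	CG	CD2	CE2	1.3906	119.346	fixed	0	-179.825
TRP	CZ3	CG	CD2	CE3	1.3659	119.795	fixed	0	179.639
TRP	CH2	CD2	CE2	CZ2	1.3773	119.806	fixed	0	0.221
TYR	CB	C	N	CA	1.5287	109.47	fixed	0	-120.041
TYR	CG	C	CA	CB	1.5062	109.497	chi	1	-120.018
TYR	CD1	CA	CB	CG	1.3823	119.947	chi	2	0.0
TYR	CD2	CA	CB	CG	1.383	119.943	chi	2	179.692
TYR	CE1	CB	CG	CD1	1.381	120.073	fixed	0	-179.976
TYR	CE2	CB	CG	CD2	1.3809	120.02	fixed	0	179.775
TYR	CZ	CG	CD1	CE1	1.3867	119.978	fixed	0	-0.102
TYR	OH	CD1	CE1	CZ	1.3582	120.13	fixed	0	-179.966
VAL	CB	C	N	CA	1.5287	109.445	fixed	0	-120.004
VAL	CG1	C	CA	CB	1.5299	109.509	chi	1	-119.986
VAL	CG2	C	CA	CB	1.5292	109.49	chi	1	0.039
HYP	CB	C	N	CA	1.5435	104.634	fixed	0	-118.766
HYP	CG	C	CA	CB	1.543	105.022	fixed	0	-142.644
HYP	CD	CA	CB	CG	1.5434	105.072	fixed	0	-0.002
HYP	OD1	CA	CB	CG	1.429	110.324	fixed	0	-118.891
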