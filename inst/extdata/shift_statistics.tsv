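# Chemical-shift reference statistics: per (residue type, atom) Gaussian
# mean and standard deviation in ppm, with a nominal observation count.
# SYNTHETIC SNAPSHOT: values compiled by hand to approximate public BMRB
# full-statistics averages for diamagnetic proteins; they are a bundled
# stand-in for live database statistics and can be overridden with
# load_statistics(path).
# columns: type atom mean sd count
A	N	123.2	3.5	10000
A	C	177.7	2.1	10000
A	CA	53.1	2.0	10000
A	CB	19.0	1.8	10000
R	N	120.8	3.7	10000
R	C	176.4	2.0	10000
R	CA	56.8	2.3	10000
R	CB	30.7	1.8	10000
R	CG	27.2	1.2	10000
R	CD	43.2	0.9	10000
N	N	118.9	4.0	10000
N	C	175.2	1.8	10000
N	CA	53.5	1.9	10000
N	CB	38.7	1.7	10000
N	CG	176.8	1.4	10000
D	N	120.6	3.9	10000
D	C	176.4	1.7	10000
D	CA	54.7	2.0	10000
D	CB	40.9	1.6	10000
D	CG	179.2	1.8	10000
C	N	118.9	4.6	10000
C	C	174.9	2.0	10000
C	CA	58.2	3.3	10000
C	CB	32.8	6.1	10000
Q	N	119.9	3.6	10000
Q	C	176.3	2.0	10000
Q	CA	56.6	2.2	10000
Q	CB	29.2	1.8	10000
Q	CG	33.7	1.2	10000
Q	CD	179.7	1.3	10000
E	N	120.6	3.5	10000
E	C	176.9	2.0	10000
E	CA	57.3	2.1	10000
E	CB	30.0	1.7	10000
E	CG	36.1	1.3	10000
E	CD	182.9	1.8	10000
G	N	109.7	3.9	10000
G	C	173.9	1.9	10000
G	CA	45.4	1.3	10000
H	N	119.6	4.0	10000
H	C	175.3	2.0	10000
H	CA	56.5	2.3	10000
H	CB	30.2	2.1	10000
H	CG	131.0	3.3	10000
H	CD2	120.1	3.3	10000
H	CE1	137.4	2.2	10000
I	N	121.5	4.3	10000
I	C	175.8	1.9	10000
I	CA	61.6	2.7	10000
I	CB	38.6	2.0	10000
I	CG1	27.7	1.8	10000
I	CG2	17.5	1.4	10000
I	CD1	13.4	1.7	10000
L	N	121.8	3.9	10000
L	C	176.9	2.0	10000
L	CA	55.6	2.2	10000
L	CB	42.3	1.9	10000
L	CG	26.8	1.2	10000
L	CD1	24.7	1.6	10000
L	CD2	24.1	1.7	10000
K	N	121.0	3.8	10000
K	C	176.6	2.0	10000
K	CA	56.9	2.2	10000
K	CB	32.8	1.8	10000
K	CG	24.9	1.2	10000
K	CD	28.9	1.2	10000
K	CE	41.9	0.9	10000
M	N	120.1	3.5	10000
M	C	176.2	2.1	10000
M	CA	56.1	2.2	10000
M	CB	32.9	2.2	10000
M	CG	32.0	1.3	10000
M	CE	17.1	1.6	10000
F	N	120.3	4.2	10000
F	C	175.5	2.0	10000
F	CA	58.1	2.6	10000
F	CB	39.9	2.1	10000
F	CG	138.4	2.0	10000
F	CD1	131.5	1.2	10000
F	CD2	131.5	1.2	10000
F	CE1	130.7	1.3	10000
F	CE2	130.7	1.3	10000
P	N	135.8	7.0	10000
P	C	176.7	1.5	10000
P	CA	63.3	1.6	10000
P	CB	31.8	1.2	10000
P	CG	27.2	1.1	10000
P	CD	50.3	1.0	10000
S	N	116.3	3.5	10000
S	C	174.6	1.7	10000
S	CA	58.7	2.1	10000
S	CB	63.8	1.5	10000
T	N	115.5	4.9	10000
T	C	174.5	1.8	10000
T	CA	62.2	2.6	10000
T	CB	69.6	1.6	10000
T	CG2	21.5	1.1	10000
W	N	121.7	4.1	10000
W	C	176.1	2.0	10000
W	CA	57.7	2.6	10000
W	CB	30.0	2.0	10000
W	CG	110.3	1.8	10000
W	CD1	126.5	1.9	10000
W	CD2	127.5	1.3	10000
W	CE2	138.5	1.3	10000
W	CE3	120.5	1.4	10000
W	CH2	123.8	1.3	10000
Y	N	120.5	4.3	10000
Y	C	175.9	2.0	10000
Y	CA	58.1	2.6	10000
Y	CB	39.3	2.2	10000
Y	CG	129.8	2.0	10000
Y	CD1	132.8	1.3	10000
Y	CD2	132.8	1.3	10000
Y	CE1	118.0	1.2	10000
Y	CE2	118.0	1.2	10000
V	N	121.1	4.8	10000
V	C	175.6	1.9	10000
V	CA	62.5	2.9	10000
V	CB	32.7	1.8	10000
V	CG1	21.5	1.4	10000
V	CG2	21.3	1.6	10000
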