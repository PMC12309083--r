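patient	age	sex	histology	localization	side	dx_date	recurrence_date	last_date	pfs	os
1	26	male	Glioblastoma	Frontalis	right	2010.03	2012.08	2014.01	28	46
2	54	female	Glioblastoma	Frontalis	left	2010.04	2013.02	2013.03	34	35
3	39	male	Glioblastoma	Parito-occipitalis	right	2010.07	2012.05	2014.06	22	47
4	47	male	Glioblastoma	Frontalis	left	2010.09	2011.01	2012.05	4	20
5	34	male	Glioblastoma	Frontalis	left	2010.12	2011.05	2011.10	6	11
6	53	male	Glioblastoma	Tempro-paritalis	left	2011.02	2011.06	2012.02	4	12
7	51	female	Oligodendroglioma-G3	Paritalis	left	2011.02	2016.03	2017.02	61	72
8	67	male	Glioblastoma	Temporalis	left	2012.02	2012.07	2013.02	5	12
9	29	male	Oligodendroglioma-G3	Fronto-paritalis	left	2012.05	2016.04	2017.09	47	64
10	67	female	Oligodendroglioma-G3	Frontalis	right	2012.06	2015.07	2015.07	37	37
11	68	male	Glioblastoma	Temporalis	left	2013.01	2014.02	2014.09	13	20
12	46	male	Glioblastoma	Frontalis	right	2019.11	2020.03	2021.02	4	15
13	77	female	Glioblastoma	Tempro-paritalis	left	2019.10	2020.06	2020.08	8	10
14	46	female	Glioblastoma	Paritalis	left	2021.01	2022.01	2022.02	1	2
15	55	male	Glioblastoma	Tempro-parito-occipitalis	right	2021.02	2021.04	2021.06	2	4
16	53	male	Glioblastoma	Frontalis	left	2021.10	2021.12	2022.02	2	3
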