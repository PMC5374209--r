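# Exosome functional gene set (27 genes) with membership flags in the two
# curated disease datasets. perturbdb stores the platform tags verbatim
# ("HD Fly; Aggreg; Cell Tox"); empty means not in the database.
row	exosome_function	dme_gene	symbol	gene_name	perturbdb	interactome
1	Release	Arf79f	ARF1|3	ADP-ribosylation factor class I		Yes
2	Release	Arf79f	ARF4|5	ADP-ribosylation factor class II	Aggreg	
3	Release	Vha68-2	ATP6V1A	ATPase, H+ transporting	Aggreg	Yes
4	Release	Vha55	ATP6V1B2	ATPase, H+ transporting		Yes
5	Release	Vha55	ATP6V1B1	ATPase, H+ transporting	Aggreg	
6	Release	Vha26	ATP6V1E1	ATPase, H+ transporting	Aggreg	Yes
7	Release	VhaSFD	ATP6V1H	ATPase, H+ transporting	Aggreg	Yes
8	Release	Myo5	MYO5A|B	Myosin V		Yes
9	Release	Rab11	RAB11A|B	Rab 11	HD Fly; Aggreg	Yes
10	Release	Syx1a	STX1A	Syntaxin 1A	HD Fly	Yes
11	Uptake	Chc	CLTC	Clathrin, heavy chain	HD Fly	Yes
12	Uptake	Shi	DNM1	Dynamin 1	HD Fly	Yes
13	Uptake	Shi	DNM2	Dynamin 2	Aggreg; Cell Tox	Yes
14	Release		YWHAB	14-3-3 family	HD Fly	Yes
15	Release		YWHAE	14-3-3 family	HD Fly; Aggreg	Yes
16	Release		YWHAZ	14-3-3 family	HD Fly; Aggreg	Yes
17	Release		YWHAG	14-3-3 family	HD Fly	Yes
18	Release		YWHAH	14-3-3 family		Yes
19	Release		YWHAQ	14-3-3 family		Yes
20	MVBs		VPS28	ESCRT-I Complex	HD Fly	
21	MVBs		VPS25	ESCRT-II Complex	HD Fly	
22	MVBs		CHMP3	ESCRT-III Complex	Aggreg	
23	MVBs		CHMP4A	ESCRT-III Complex	Aggreg	
24	MVBs		CHMP4B	ESCRT-III Complex	HD Fly; Aggreg	Yes
25	MVBs		CHMP5	ESCRT-IV Complex		Yes
26	MVBs		VPS4A	ESCRT-IV Complex	Aggreg; Cell Tox	
27	MVBs		VPS4B	ESCRT-IV Complex	Aggreg	
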