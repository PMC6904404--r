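2950159	Berlin	berlin		52.52437	13.41053	DE	3426354
2644688	Leeds	leeds		53.79648	-1.54785	GB	455123
4951788	Springfield	springfield		42.10148	-72.58981	US	167000
2149761	Springfield	springfield		-32.71667	151.93333	AU	5000
2867714	Münster	munster	Muenster	51.96236	7.62571	DE	270184
2988507	Paris	paris		48.85341	2.34880	FR	2138551
3173435	Milan	milan	Milano	45.46427	9.18951	IT	1236837
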