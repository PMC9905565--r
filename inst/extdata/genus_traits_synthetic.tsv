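genus	body_length_mm	morphogroup
Agrenia	1.4	entomobryomorpha
Allacma	2.4	symphypleona
Anurida	1.8	poduromorpha
Anurophorus	0.9	entomobryomorpha
Archisotoma	0.8	entomobryomorpha
Arrhopalites	0.7	symphypleona
Ballistura	1.0	entomobryomorpha
Bourletiella	1.1	symphypleona
Brachystomella	0.9	poduromorpha
Ceratophysella	1.1	poduromorpha
Cryptopygus	0.9	entomobryomorpha
Cyphoderus	1.0	entomobryomorpha
Desoria	1.6	entomobryomorpha
Deuteraphorura	1.5	poduromorpha
Deuterosminthurus	0.9	symphypleona
Dicyrtoma	1.6	symphypleona
Dicyrtomina	1.4	symphypleona
Entomobrya	2.0	entomobryomorpha
Folsomia	1.2	entomobryomorpha
Folsomides	0.5	entomobryomorpha
Friesea	0.8	poduromorpha
Heteromurus	1.8	entomobryomorpha
Hypogastrura	1.3	poduromorpha
Isotoma	2.2	entomobryomorpha
Isotomiella	0.7	entomobryomorpha
Isotomurus	2.3	entomobryomorpha
Katianna	0.8	symphypleona
Lepidocyrtus	1.5	entomobryomorpha
Megalothorax	0.4	neelipleona
Mesaphorura	0.6	poduromorpha
Micranurida	0.5	poduromorpha
Neanura	2.3	poduromorpha
Neelides	0.4	neelipleona
Neelus	0.5	neelipleona
Odontella	0.9	poduromorpha
Onychiurus	1.7	poduromorpha
Orchesella	3.2	entomobryomorpha
Parisotoma	1.0	entomobryomorpha
Paratullbergia	0.7	poduromorpha
Pogonognathellus	4.5	entomobryomorpha
Proisotoma	1.1	entomobryomorpha
Protaphorura	1.8	poduromorpha
Pseudachorutes	1.2	poduromorpha
Pseudosinella	1.1	entomobryomorpha
Ptenothrix	1.5	symphypleona
Seira	2.1	entomobryomorpha
Sinella	1.3	entomobryomorpha
Sminthurides	0.6	symphypleona
Sminthurinus	0.8	symphypleona
Sminthurus	2.2	symphypleona
Sphaeridia	0.4	symphypleona
Stenaphorura	0.8	poduromorpha
Tetracanthella	1.1	entomobryomorpha
Tomocerus	3.8	entomobryomorpha
Tullbergia	0.8	poduromorpha
Vertagopus	1.2	entomobryomorpha
Willemia	0.5	poduromorpha
Willowsia	1.7	entomobryomorpha
Xenylla	1.0	poduromorpha
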