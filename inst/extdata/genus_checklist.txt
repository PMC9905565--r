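Agrenia
Allacma
Anurida
Anurophorus
Archisotoma
Arrhopalites
Ballistura
Bourletiella
Brachystomella
Ceratophysella
Cryptopygus
Cyphoderus
Desoria
Deuteraphorura
Deuterosminthurus
Dicyrtoma
Dicyrtomina
Entomobrya
Folsomia
Folsomides
Friesea
Heteromurus
Hypogastrura
Isotoma
Isotomiella
Isotomurus
Katianna
Lepidocyrtus
Megalothorax
Mesaphorura
Micranurida
Neanura
Neelides
Neelus
Odontella
Onychiurus
Orchesella
Parisotoma
Paratullbergia
Pogonognathellus
Proisotoma
Protaphorura
Pseudachorutes
Pseudosinella
Ptenothrix
Seira
Sinella
Sminthurides
Sminthurinus
Sminthurus
Sphaeridia
Stenaphorura
Tetracanthella
Tomocerus
Tullbergia
Vertagopus
Willemia
Willowsia
Xenylla
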