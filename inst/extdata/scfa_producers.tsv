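genus	phylum	scfa
Bifidobacterium	Actinobacteria	Acetate
Alistipes	Bacteroidetes	Propionate
Bacteroides	Bacteroidetes	Propionate
Prevotella	Bacteroidetes	Propionate
Anaerostipes	Firmicutes	Butyrate
Blautia	Firmicutes	Propionate
Coprococcus	Firmicutes	Propionate and butyrate
Dialister	Firmicutes	Propionate
Eubacterium hallii group	Firmicutes	Propionate and butyrate
Eubacterium rectale group	Firmicutes	Butyrate
Faecalibacterium	Firmicutes	Butyrate
Holdemanella	Firmicutes	Butyrate
Phascolarctobacterium	Firmicutes	Propionate
Roseburia	Firmicutes	Propionate and butyrate
Subdoligranulum	Firmicutes	Butyrate
Desulfovibrio	Proteobacteria	Acetate
Akkermansia	Verrucomicrobia	Propionate and acetate
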