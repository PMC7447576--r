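# Demonstration lexicon for desk-scale runs, examples and simulations.
# SYNTHETIC stand-in: the production dictionaries of the original mining
# systems are not published; this file only covers a small plant-biology
# vocabulary so that the pipeline can be exercised without downloads.
# Format: row type<TAB>fields (BIOENTITY surface normalized class |
# TERM term | CONCEPT term | TAXON synonym taxid)
BIOENTITY	rbcL	rbcL	protein
BIOENTITY	psbA	psbA	protein
BIOENTITY	matK	matK	protein
BIOENTITY	PR-1	PR-1	protein
BIOENTITY	PR-2	PR-2	protein
BIOENTITY	PR-5	PR-5	protein
BIOENTITY	NPR1	NPR1	protein
BIOENTITY	PDF1.2	PDF1.2	gene
BIOENTITY	RPS2	RPS2	protein
BIOENTITY	RPS4	RPS4	protein
BIOENTITY	EDS1	EDS1	protein
BIOENTITY	PAD4	PAD4	protein
BIOENTITY	RPM1	RPM1	protein
BIOENTITY	RIN4	RIN4	protein
BIOENTITY	MPK4	MPK4	protein
BIOENTITY	MPK6	MPK6	protein
BIOENTITY	ORA59	ORA59	protein
BIOENTITY	ERF1	ERF1	protein
BIOENTITY	MYC2	MYC2	gene
BIOENTITY	COI1	COI1	protein
BIOENTITY	PEPR1	PEPR1	protein
BIOENTITY	LOX2	LOX2	gene
BIOENTITY	AOS	AOS	gene
BIOENTITY	TGA	TGA	protein
BIOENTITY	GRX480	GRX480	gene
BIOENTITY	EIN3	EIN3	protein
BIOENTITY	EIL1	EIL1	protein
BIOENTITY	chlB	chlB	gene
BIOENTITY	chlL	chlL	gene
BIOENTITY	chlN	chlN	gene
BIOENTITY	NaD1	NaD1	protein
BIOENTITY	NaD2	NaD2	protein
BIOENTITY	CaM	CaM	protein
BIOENTITY	CAT2	CAT2	protein
BIOENTITY	GBF1	GBF1	protein
BIOENTITY	glutathione S-transferase	glutathione S-transferase	protein
BIOENTITY	GST	GST	protein
BIOENTITY	transferase	transferase	protein
BIOENTITY	lipid transfer protein	lipid transfer protein	protein
BIOENTITY	LTP	LTP	protein
BIOENTITY	leaf	leaf	tissue
BIOENTITY	root	root	tissue
BIOENTITY	mesophyll cell	mesophyll cell	cell_type
BIOENTITY	guard cell	guard cell	cell_type
TERM	activates
TERM	activate
TERM	activated
TERM	binds
TERM	interacts
TERM	interacts with
TERM	inhibits
TERM	inhibited
TERM	induces
TERM	induced
TERM	induction
TERM	encoding
TERM	encode
TERM	encodes
TERM	encoded
TERM	amplified
TERM	amplifies
TERM	required
TERM	requires
TERM	enhanced
TERM	enhances
TERM	regulates
TERM	regulated
TERM	regulation
TERM	phosphorylates
TERM	suppresses
TERM	suppressed
TERM	represses
TERM	modulates
TERM	stabilizes
TERM	degrades
TERM	cleaves
TERM	transcribes
TERM	associates
TERM	upregulates
TERM	downregulates
TERM	promotes
TERM	triggers
TERM	mediates
TERM	stimulates
CONCEPT	biotic stress
CONCEPT	defense response
CONCEPT	photosystem II
CONCEPT	signaling
CONCEPT	transcription
CONCEPT	chloroplast
CONCEPT	pathogen resistance
CONCEPT	jasmonic acid
CONCEPT	salicylic acid
CONCEPT	ethylene
TAXON	Glycine max	3847
TAXON	soybean	3847
TAXON	Arabidopsis thaliana	3702
TAXON	thale cress	3702
TAXON	Zea mays	4577
TAXON	maize	4577
TAXON	Brachypodium distachyon	15368
TAXON	Nicotiana tabacum	4097
TAXON	Solanum tuberosum	4113
TAXON	potato	4113
TAXON	Solanum lycopersicum	4081
TAXON	tomato	4081
TAXON	Phaseolus vulgaris	3885
TAXON	Lotus japonicus	34305
TAXON	Cicer arietinum	3827
TAXON	Manihot esculenta	3983
TAXON	Selaginella moellendorffii	88036
TAXON	Medicago truncatula	3880
TAXON	Nicotiana benthamiana	4100
TAXON	Ricinus communis	3988
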