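term	hypernym	source	semantic_type
# Small hand-written demonstration lexicon (synthetic example content).
lymphoma	cancer	wordnet
lymphoma	neoplastic process	semantic_type	Neoplastic Process
carcinoma	cancer	wordnet
histamine	amine	wordnet
histamine receptor	organ	semantic_type	Receptor
erythrocyte	cell	wordnet
erythrocyte	blood cell	semantic_type	Cell
hypertension	disease	semantic_type	Disease or Syndrome
myocardial infarction	heart attack	custom
corticosteroid	hormone	wordnet
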