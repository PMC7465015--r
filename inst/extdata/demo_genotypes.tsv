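individual	breed	marker	copies
N01	Norfolk	siteA	2
N02	Norfolk	siteA	2
N03	Norfolk	siteA	1
N04	Norfolk	siteA	1
N05	Norfolk	siteA	0
N06	Norfolk	siteA	0
N07	Norfolk	siteA	0
N08	Norfolk	siteA	0
N09	Norfolk	siteA	0
N10	Norfolk	siteA	0
S01	Skye	siteA	1
S02	Skye	siteA	0
S03	Skye	siteA	0
S04	Skye	siteA	0
S05	Skye	siteA	0
S06	Skye	siteA	0
S07	Skye	siteA	0
S08	Skye	siteA	0
S09	Skye	siteA	0
S10	Skye	siteA	0
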