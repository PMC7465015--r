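chrA	9900	10200	ECR1	500	+
chrA	99500	99800	ECR2	500	+
chrA	149000	149400	ECR3	500	+
chrB	49000	49350	ECR4	500	+
chrB	99800	100150	ECR5	500	+
chrB	100900	101200	ECR6	500	+
chrB	149500	149900	ECR7	500	+
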