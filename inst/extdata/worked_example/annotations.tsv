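gene_id	class	is_wfrg
g1	other	TRUE
g2	other	TRUE
g3	other	TRUE
g4	other	TRUE
g5	hormone	FALSE
g6	other	FALSE
g7	TF	FALSE
g8	other	FALSE
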