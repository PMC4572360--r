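go_id	name
GO:0005634	nucleus
GO:0005737	cytoplasm
GO:0005886	plasma membrane
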