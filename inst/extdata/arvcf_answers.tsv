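system	rank	go_id	name	correct
GoPubMed	1	GO:0005694	chromosome	0
GoPubMed	2	GO:0005737	cytoplasm	1
GoPubMed	3	GO:0016020	membrane	0
GoPubMed	4	GO:0005912	adherens junction	0
GoPubMed	5	GO:0005886	plasma membrane	1
EAGL	1	GO:0005912	adherens junction	0
EAGL	2	GO:0005915	zonula adherens	0
EAGL	3	GO:0005923	tight junction	0
EAGL	4	GO:0005886	plasma membrane	1
EAGL	5	GO:0005694	chromosome	0
GOCat	1	GO:0005634	nucleus	1
GOCat	2	GO:0005737	cytoplasm	1
GOCat	3	GO:0005886	plasma membrane	1
GOCat	4	GO:0005911	cell-cell junction	0
GOCat	5	GO:0005913	cell-cell adherens junction	0
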