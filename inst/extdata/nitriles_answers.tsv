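system	rank	go_id	name	correct
GoPubMed	1	GO:0005488	binding	1
GoPubMed	2	GO:0004707	MAP kinase activity	0
GoPubMed	3	GO:0004871	signal transducer activity	1
GoPubMed	4	GO:0003824	catalytic activity	1
GoPubMed	5	GO:0031993	light transducer activity	0
GoPubMed	6	GO:0060089	molecular transducer activity	1
GoPubMed	7	GO:0047322	[hydroxymethylglutaryl-CoA reductase (NADPH)] kinase activity	0
GoPubMed	8	GO:0050405	[acetyl-CoA carboxylase] kinase activity	0
GoPubMed	9	GO:0033736	L-lysine 6-oxidase activity	0
GoPubMed	10	GO:0005138	interleukin-6 receptor binding	0
EAGL	1	GO:0005128	erythropoietin receptor binding	0
EAGL	2	GO:0018822	nitrile hydratase activity	0
EAGL	3	GO:0003824	catalytic activity	1
EAGL	4	GO:0004601	peroxidase activity	1
EAGL	5	GO:0004096	catalase activity	0
EAGL	6	GO:0052716	hydroquinone:oxygen oxidoreductase activity	0
EAGL	7	GO:0000257	nitrilase activity	0
EAGL	8	GO:0033968	glutaryl-7-aminocephalosporanic-acid acylase activity	0
EAGL	9	GO:0004806	triglyceride lipase activity	0
EAGL	10	GO:0005344	oxygen transporter activity	0
GOCat	1	GO:0005515	protein binding	1
GOCat	2	GO:0042803	protein homodimerization activity	1
GOCat	3	GO:0008270	zinc ion binding	0
GOCat	4	GO:0000287	magnesium ion binding	0
GOCat	5	GO:0003677	DNA binding	1
GOCat	6	GO:0003700	sequence-specific DNA binding transcription factor activity	1
GOCat	7	GO:0030170	pyridoxal phosphate binding	1
GOCat	8	GO:0008144	drug binding	1
GOCat	9	GO:0020037	heme binding	1
GOCat	10	GO:0004674	protein serine/threonine kinase activity	1
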