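Pyrimidine metabolism	pyrimidine nucleotide synthesis and degradation	uracil	uridine	cytidine	thymidine	dihydrouracil	orotate	UMP	CMP
TCA cycle	tricarboxylic acid cycle intermediates	citrate	aconitate	isocitrate	alpha-ketoglutarate	succinate	fumarate	malate	oxaloacetate
Glycolysis	glucose catabolism to pyruvate	glucose	glucose-6-phosphate	fructose-6-phosphate	fructose-1,6-bisphosphate	DHAP	3-phosphoglycerate	phosphoenolpyruvate	pyruvate	lactate
Glycerolipids	glycerolipid backbone metabolites	glycerol	glycerol-3-phosphate	glycerophosphocholine	glycerophosphoethanolamine
Amino acids	proteinogenic amino acids	alanine	aspartate	glutamate	glycine	serine	proline	leucine	isoleucine	valine	threonine
Microbiota-derived	metabolites of microbial origin	hippurate	indoxyl-sulfate	p-cresol-sulfate	phenylacetylglutamine	TMAO
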