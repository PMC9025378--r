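taxon	rank	trophic_mode	guild	confidence
Meira	genus	Pathotroph	Animal Pathogen	Probable
Sympodiomycopsis	genus	Symbiotroph	Epiphyte	Possible
Meyerozyma	genus	Saprotroph	Undefined Saprotroph	Probable
Trichoderma	genus	Saprotroph;Pathotroph	Mycoparasite-Undefined Saprotroph	Highly Probable
Colletotrichum gloeosporioides	species	Pathotroph	Plant Pathogen	Highly Probable
Colletotrichum	genus	Pathotroph	Plant Pathogen	Probable
Fusarium	genus	Pathotroph;Saprotroph	Plant Pathogen-Wood Saprotroph	Probable
Exobasidium	genus	Pathotroph	Plant Pathogen	Highly Probable
Agaricales	order	Saprotroph	Undefined Saprotroph	Possible
Polyporales	order	Saprotroph	Wood Saprotroph	Probable
Ascomycota	phylum	Saprotroph	Undefined Saprotroph	Possible
Xylaria	genus	Saprotroph	Wood Saprotroph	Probable
Oidium heveae	species	Pathotroph	Plant Pathogen	Highly Probable
Glomus	genus	Symbiotroph	Arbuscular Mycorrhizal	Highly Probable
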