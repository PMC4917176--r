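rtype	entries	source
DB	194	databases.biomedcentral.com
SW	262	www.bioinformatik.de
PK	1013	www.bioconductor.org
SW	2101	www.bioinformatics.ca/links_directory
SW	385	evolution.genetics.washington.edu/phylip/software.html
DB	506	www.ebi.ac.uk/miriam/main
DB	1510	www.oxfordjournals.org/nar/database/a
SW	134	www.netsci.org/Resources/Software/Bioinform
DB	358	bioportal.bioontology.org/ontologies
SW	38	www.bioinf.manchester.ac.uk/recombination/programs.shtml
SW	1196	en.wikipedia.org/wiki/Wiki
unknown	517	manually_generated
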