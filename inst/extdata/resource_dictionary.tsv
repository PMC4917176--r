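BLAST	SW	curated_sw	Basic Local Alignment Search Tool
ClustalW	SW	curated_sw	
Clustal Omega	SW	curated_sw	
MUSCLE	SW	curated_sw	Multiple Sequence Comparison by Log Expectation
MAFFT	SW	curated_sw	
T-Coffee	SW	curated_sw	
HMMER	SW	curated_sw	
BWA	SW	curated_sw	Burrows-Wheeler Aligner
Bowtie	SW	curated_sw	
Bowtie2	SW	curated_sw	
TopHat	SW	curated_sw	
Cufflinks	SW	curated_sw	
STAR	SW	curated_sw	Spliced Transcripts Alignment to a Reference
HISAT	SW	curated_sw	
SAMtools	SW	curated_sw	
BCFtools	SW	curated_sw	
Picard	SW	curated_sw	
GATK	SW	curated_sw	Genome Analysis Toolkit
FreeBayes	SW	curated_sw	
VarScan	SW	curated_sw	
ANNOVAR	SW	curated_sw	
SnpEff	SW	curated_sw	
BEDTools	SW	curated_sw	
IGV	SW	curated_sw	Integrative Genomics Viewer
UCSC Genome Browser	SW	curated_sw	
Galaxy	SW	curated_sw	
Taverna	SW	curated_sw	
Cytoscape	SW	curated_sw	
Gephi	SW	curated_sw	
ImageJ	SW	curated_sw	
Fiji	SW	curated_sw	
CellProfiler	SW	curated_sw	
PyMOL	SW	curated_sw	
Chimera	SW	curated_sw	
VMD	SW	curated_sw	Visual Molecular Dynamics
GROMACS	SW	curated_sw	
AMBER	SW	curated_sw	Assisted Model Building with Energy Refinement
CHARMM	SW	curated_sw	Chemistry at Harvard Macromolecular Mechanics
NAMD	SW	curated_sw	
AutoDock	SW	curated_sw	
MODELLER	SW	curated_sw	
Phyre	SW	curated_sw	
I-TASSER	SW	curated_sw	
Rosetta	SW	curated_sw	
PHYLIP	SW	curated_sw	Phylogeny Inference Package
PAUP	SW	curated_sw	Phylogenetic Analysis Using Parsimony
MrBayes	SW	curated_sw	
BEAST	SW	curated_sw	Bayesian Evolutionary Analysis Sampling Trees
RAxML	SW	curated_sw	Randomized Axelerated Maximum Likelihood
PhyML	SW	curated_sw	
MEGA	SW	curated_sw	Molecular Evolutionary Genetics Analysis
FastTree	SW	curated_sw	
TreeView	SW	curated_sw	
FigTree	SW	curated_sw	
Primer3	SW	curated_sw	
Geneious	SW	curated_sw	
CLC Genomics Workbench	SW	curated_sw	
Velvet	SW	curated_sw	
SPAdes	SW	curated_sw	
ABySS	SW	curated_sw	
SOAPdenovo	SW	curated_sw	
Trinity	SW	curated_sw	
Oases	SW	curated_sw	
Canu	SW	curated_sw	
MIRA	SW	curated_sw	
Newbler	SW	curated_sw	
Phred	SW	curated_sw	
Phrap	SW	curated_sw	
Consed	SW	curated_sw	
RepeatMasker	SW	curated_sw	
AUGUSTUS	SW	curated_sw	
GeneMark	SW	curated_sw	
Glimmer	SW	curated_sw	
SignalP	SW	curated_sw	
TMHMM	SW	curated_sw	
InterProScan	SW	curated_sw	
PSORT	SW	curated_sw	
NetPhos	SW	curated_sw	
Mascot	SW	curated_sw	
SEQUEST	SW	curated_sw	
MaxQuant	SW	curated_sw	
Skyline	SW	curated_sw	
Xcalibur	SW	curated_sw	
OpenMS	SW	curated_sw	
Trans-Proteomic Pipeline	SW	curated_sw	
mothur	SW	curated_sw	
QIIME	SW	curated_sw	Quantitative Insights Into Microbial Ecology
UPARSE	SW	curated_sw	
MetaPhlAn	SW	curated_sw	
MG-RAST	SW	curated_sw	
FastQC	SW	curated_sw	
Trimmomatic	SW	curated_sw	
Cutadapt	SW	curated_sw	
MACS	SW	curated_sw	Model-based Analysis of ChIP-Seq
HOMER	SW	curated_sw	
MEME	SW	curated_sw	Multiple Em for Motif Elicitation
JASPAR	DB	curated_db	
R	SW	curated_sw	
Bioconductor	PK	curated_pk	
limma	PK	curated_pk	
edgeR	PK	curated_pk	
DESeq	PK	curated_pk	
DESeq2	PK	curated_pk	
affy	PK	curated_pk	
ggplot2	PK	curated_pk	
Shiny	PK	curated_pk	
vegan	PK	curated_pk	
ape	PK	curated_pk	
phyloseq	PK	curated_pk	
WGCNA	PK	curated_pk	Weighted Gene Co-expression Network Analysis
GSEA	SW	curated_sw	Gene Set Enrichment Analysis
DAVID	SW	curated_sw	Database for Annotation Visualization and Integrated Discovery
g:Profiler	SW	curated_sw	
SPSS	SW	curated_sw	Statistical Package for the Social Sciences
Stata	SW	curated_sw	
SAS	SW	curated_sw	Statistical Analysis System
MATLAB	SW	curated_sw	
GraphPad Prism	SW	curated_sw	
Microsoft Excel	SW	curated_sw	
Python	SW	curated_sw	
BioPerl	PK	curated_pk	
Biopython	PK	curated_pk	
BioJava	PK	curated_pk	
Weka	SW	curated_sw	Waikato Environment for Knowledge Analysis
Orange	SW	curated_sw	
KNIME	SW	curated_sw	Konstanz Information Miner
GenBank	DB	curated_db	
RefSeq	DB	curated_db	Reference Sequence
EMBL	DB	curated_db	European Molecular Biology Laboratory
DDBJ	DB	curated_db	DNA Data Bank of Japan
UniProt	DB	curated_db	Universal Protein Resource
SWISS-PROT	DB	curated_db	
TrEMBL	DB	curated_db	
PDB	DB	curated_db	Protein Data Bank
SCOP	DB	curated_db	Structural Classification of Proteins
CATH	DB	curated_db	Class Architecture Topology Homology
Pfam	DB	curated_db	
PROSITE	DB	curated_db	
InterPro	DB	curated_db	
SMART	DB	curated_db	Simple Modular Architecture Research Tool
KEGG	DB	curated_db	Kyoto Encyclopedia of Genes and Genomes
Reactome	DB	curated_db	
BioCyc	DB	curated_db	
MetaCyc	DB	curated_db	
STRING	DB	curated_db	Search Tool for the Retrieval of Interacting Genes
BioGRID	DB	curated_db	Biological General Repository for Interaction Datasets
IntAct	DB	curated_db	
MINT	DB	curated_db	Molecular Interaction Database
HPRD	DB	curated_db	Human Protein Reference Database
GEO	DB	curated_db	Gene Expression Omnibus
ArrayExpress	DB	curated_db	
SRA	DB	curated_db	Sequence Read Archive
dbSNP	DB	curated_db	
dbGaP	DB	curated_db	
ClinVar	DB	curated_db	
COSMIC	DB	curated_db	Catalogue of Somatic Mutations in Cancer
OMIM	DB	curated_db	Online Mendelian Inheritance in Man
HGMD	DB	curated_db	Human Gene Mutation Database
Ensembl	DB	curated_db	
BioMart	DB	curated_db	
Entrez	DB	curated_db	
PubMed	DB	curated_db	
MEDLINE	DB	curated_db	
PubMed Central	DB	curated_db	
Scopus	DB	curated_db	
Web of Science	DB	curated_db	
ClinicalTrials.gov	DB	curated_db	
DrugBank	DB	curated_db	
ChEMBL	DB	curated_db	
PubChem	DB	curated_db	
ZINC	DB	curated_db	
HMDB	DB	curated_db	Human Metabolome Database
TAIR	DB	curated_db	The Arabidopsis Information Resource
FlyBase	DB	curated_db	
WormBase	DB	curated_db	
ZFIN	DB	curated_db	Zebrafish Information Network
MGD	DB	curated_db	Mouse Genome Database
SGD	DB	curated_db	Saccharomyces Genome Database
RGD	DB	curated_db	Rat Genome Database
EcoCyc	DB	curated_db	
Gramene	DB	curated_db	
Phytozome	DB	curated_db	
miRBase	DB	curated_db	
Rfam	DB	curated_db	
tRNAdb	DB	curated_db	
GtRNAdb	DB	curated_db	
SILVA	DB	curated_db	
Greengenes	DB	curated_db	
RDP	DB	curated_db	Ribosomal Database Project
IMG	DB	curated_db	Integrated Microbial Genomes
PATRIC	DB	curated_db	
VFDB	DB	curated_db	Virulence Factor Database
CARD	DB	curated_db	Comprehensive Antibiotic Resistance Database
Panther	DB	curated_db	
TreeFam	DB	curated_db	
OrthoMCL	SW	curated_sw	
eggNOG	DB	curated_db	
HGNC	DB	curated_db	HUGO Gene Nomenclature Committee
GO	ONT	curated_ont	Gene Ontology
ChEBI	ONT	curated_ont	Chemical Entities of Biological Interest
HPO	ONT	curated_ont	Human Phenotype Ontology
MeSH	ONT	curated_ont	Medical Subject Headings
SNOMED CT	ONT	curated_ont	
ICD	ONT	curated_ont	International Classification of Diseases
UMLS	ONT	curated_ont	Unified Medical Language System
FMA	ONT	curated_ont	Foundational Model of Anatomy
OBO	ONT	curated_ont	Open Biomedical Ontologies
EDAM	ONT	curated_ont	
Cluster	SW	ambiguous	
Express	SW	ambiguous	
Image	SW	ambiguous	
Match	SW	ambiguous	
Profile	SW	ambiguous	
Prime	SW	ambiguous	
Origin	SW	ambiguous	
Scale	SW	ambiguous	
Tree	SW	ambiguous	
Amber	SW	ambiguous	
Basic	SW	ambiguous	
Spring	SW	ambiguous	
Gap	SW	ambiguous	
Cell	DB	ambiguous	
Model	SW	ambiguous	
Anchor	SW	ambiguous	
Vector	SW	ambiguous	
Signal	SW	ambiguous	
Domain	DB	ambiguous	
Factor	SW	ambiguous	
analysis	PK	ambiguous	
genomes	PK	ambiguous	
clustering	SW	ambiguous	
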