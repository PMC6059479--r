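category	term
DNA binding	DNA-templated transcription, initiation
DNA binding	DNA-templated transcription, elongation
DNA binding	DNA-templated transcription, termination
DNA binding	transcription from RNA polymerase I promoter
DNA binding	transcription from RNA polymerase II promoter
DNA binding	chromatin organisation
DNA binding	histone modification
DNA binding	DNA replication
DNA binding	DNA recombination
DNA binding	DNA repair
DNA binding	cellular response to DNA damage stimulus
DNA binding	regulation of DNA metabolic process
DNA binding	nuclear transport
DNA binding	chromosome segregation
RNA binding or processing	mRNA processing
RNA binding or processing	rRNA processing
RNA binding or processing	tRNA processing
RNA binding or processing	RNA modification
RNA binding or processing	RNA splicing
RNA binding or processing	RNA catabolic process
metabolism	carbohydrate metabolic process
metabolism	cofactor metabolic process
metabolism	nucleobase-containing small-molecule metabolic process
metabolism	monocarboxylic acid metabolic process
metabolism	cellular amino acid metabolic process
metabolism	generation of precursor metabolites and energy
metabolism	oligosaccharide metabolic process
metabolism	lipid metabolic process
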