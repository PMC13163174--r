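# Synthetic miniature of a protein database: three entries following the
# schema in uniprot_demo.yaml; two entries are human (taxonomy 9606).
@prefix up: <http://purl.uniprot.org/core/> .
@prefix uniprot: <http://purl.uniprot.org/uniprot/> .
@prefix taxonomy: <http://purl.uniprot.org/taxonomy/> .
@prefix citations: <http://purl.uniprot.org/citations/> .

uniprot:Q9BYF1 a up:Protein .
uniprot:Q9BYF1 up:organism taxonomy:9606 .
uniprot:Q9BYF1 up:citation citations:15174051 .
uniprot:P12345 a up:Protein .
uniprot:P12345 up:organism taxonomy:9606 .
uniprot:P12345 up:citation citations:23792563 .
uniprot:P67890 a up:Protein .
uniprot:P67890 up:organism taxonomy:10090 .
uniprot:P67890 up:citation citations:11111111 .
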