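name: uniprot
prefixes:
  up: <http://purl.uniprot.org/core/>
  uniprot: <http://purl.uniprot.org/uniprot/>
  taxonomy: <http://purl.uniprot.org/taxonomy/>
  citations: <http://purl.uniprot.org/citations/>
model:
  - UniProt up:Q9BYF1:
      - a: up:Protein
      - explanation: "Protein entry ID in the UniProt database."
      - up:organism:
          uniprot_taxonomy: taxonomy:9606
          explanation: "Taxonomy ID of the organism the protein belongs to."
      - up:citation:
          uniprot_citation: citations:15174051
          explanation: "Citation ID of the literature describing the protein."
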