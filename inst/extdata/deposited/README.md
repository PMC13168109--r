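# Deposited genome fixtures (not bundled)

The acceptance tests for the published *Xanthomonas*-phage results need the
deposited sequence sets, which must be downloaded from GenBank / the ICTV
Virus Metadata Resource and are therefore not shipped with the package.
Place the following plain-text files in this directory to enable them:

- `genomes_15.fasta` — nucleotide FASTA of the 15 deposited phage genomes,
  accessions PP391659-PP391664 and PX630731-PX630739, headers starting with
  the accession.
- `PP391659.fasta` — the single accession PP391659 (44,947 bp).
- `proteins_15.faa` — protein FASTA for the 15 genomes with
  `genomeID|geneID` headers (CDS translations from the GenBank records; see
  `read_genbank_cds()`).
- `proteins_45.faa` — protein FASTA for the full 45-genome comparative set
  (the 15 genomes above, NEB7, and the related phages selected from ICTV
  VMR MSL40), same header dialect.
- `groupings_45.tsv` — tab-separated table with columns `genome_id`,
  `genus`, `subfamily` assigning each of the 45 genomes to its
  (proposed) taxon, including `Duraznoxanthovirus` and `Kantovirinae`.

Without these files the corresponding acceptance tests fail with a message
pointing here; all synthetic-data tests are self-contained.
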