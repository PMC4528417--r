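# Worked-example inputs (not shipped)

The optional worked-example checks in the test suite classify published
clonal B-cell sequences against the full human IGH reference. Both inputs
are third-party data that cannot be redistributed here:

* `human_igh.json` — a reference bundle built from the IMGT human IGH
  reference directory (F+ORF), e.g.:

      vdjplace build-ref --v IGHV.fasta --j IGHJ.fasta --d IGHD.fasta \
        --boundaries boundaries.json -o human_igh.json

* `queries.fasta` — GenBank sequences to classify; the tests look for the
  accession `AF262201` (tonsillar B-cell clone) by record name.

Drop both files into this directory (in the installed package or before
installation) and the corresponding tests activate automatically.
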