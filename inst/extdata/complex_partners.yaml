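# Curated nuclear multi-subunit-complex partners of plastid candidate loci.
accD:
  - complex: heteromeric acetyl-CoA carboxylase (ACCase)
    partners:
      - biotin carboxyl carrier protein (BCCP)
      - biotin carboxylase (BC)
      - alpha subunit of carboxyltransferase (alpha-CT)
    keywords:
      - biotin carboxyl carrier
      - biotin carboxylase
      - carboxyltransferase
      - acetyl-CoA carboxylase
rpoB:
  - complex: plastid-encoded RNA polymerase (PEP)
    partners:
      - sigma factors
      - CSP41
      - iron superoxide dismutase 3 (FeSOD3)
      - plastid transcription kinase (PTK)
    keywords:
      - sigma factor
      - CSP41
      - superoxide dismutase
      - transcription kinase
ycf1:
  - complex: TIC preprotein import complex (Tic214)
    partners:
      - Tic100
      - Tic56
      - Tic20-I
    keywords:
      - Tic100
      - Tic56
      - Tic20
      - preprotein import
ycf2: []
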