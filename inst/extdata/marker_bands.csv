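name,lo_cm-1,hi_cm-1,assignment
calcium_oxalate,740,800,calcium oxalate monohydrate C-C/C-O modes (779 cm-1)
a_n_beta_sheet,931,983,poly-alanine (A)n antiparallel beta-sheet (961 cm-1)
ag_n_beta_sheet,984,1006,poly(alanine-glycine) (AG)n beta-sheet (975/998 cm-1)
phenolics,1094,1135,tannin / polyphenol C-C aromatic stretching
sericin,1384,1403,serine-rich sericin CH2/COO modes
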