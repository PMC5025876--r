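>VH186.2-synthetic
GAAGTTCAGCTGCAGCAGAGCGGTCCTGAACTGGTTAAACCTGGTGCTAGCGTTAAAATTAGCTGTAAAGCTAGCGGTTA
TACATTTACAGATTATTGGATTAATTGGGTTAAACAGCGTCCTGGTCAGGGTCTGGAATGGATTGGTCGTATTTATCCTG
GTAATGGTGATACAGGTCGTGTTTATAATCAGAAATTTAAAGGTAAAGCTACACTGACAGTTGATAAAAGCAGCAGCACA
GCTTATATGGAACTGCGTAGCCTGACAAGCGAAGATAGCGCTGTTTATTATTGT
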