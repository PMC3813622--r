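>demo_plasmid
CTTGAACCCTCAAGCCTGCAGGCCCGAATCACCAACATACTTGACATAGTCGAGCATTTC
ACCTCTGGTTCGGGGTACAAAAGGCCAATGTATTTTCTCCACAGTGAGGGCCGTGACGCA
GTCAGAGTTTGTGTAATACGTCTTCGTTGAATGGTGACGTTTCAGTACACACCTGGTGTG
GTCCAATCAACACAGACGGTTCCACGTGCTGTCTTAAAGCAGCGCACAACGATCAGGTCT
CCAACTCGAAAATTAGGTATGAGTCAAATTAGCCTCCATGGTTCGACATTGCATCCTAGG
CGATCTTTGACTGAAGCTACCCAACACGTGGCGCGTGCTTCCTCCTTCGCATTAGATCCG
TTCGACAATGGTTACAAATCTATGGTGAACACAAGGAGTTATCGGTGCCCATATAGCACC
CGGCTAACGCGAGAAGTTTCTCGAGATTTCTAAGTGCTATCCCCTGACTATAATAGTAGG
GGGGTTAGTGTGTACGGGTACTTGGTGAAGTGGTAGTTAGCAAGGTGCAGACAATTGCGC
GAGGTAGTTAGAAGCTTCGCAGGCCGACCCAGGTGATCATTTACGGGCATATTACCTCGA
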