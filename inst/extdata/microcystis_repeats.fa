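>DR1
GTTCCAATTAATCTTAAACCCTATTAGGGATTGAAAC
>DR1a
GTTTCAATCCCTAATAGGGTTTAAGATTAATTGGAAC
>DR1b
GTTCCAATTAATCTTAAACCCTACTAGGGATTGAAAC
>DR1ab
GTTTCAATCCCTAGTAGGGTTTAAGATTAATTGGAAC
>DR2
CTTGCTTCCAATTCGTGAAGCGTATGAATGGAAAC
>DR2a
GTTTCCATTCATACGCTTCACGAATTGGAAGCAAG
>DR3
CTCTCTACTCGCTAGAGAAATTAATTGAATGGAAAC
>DR3a
GTTTCCATTCAATTAATTTCTCTAGCGAGTAGAGAG
>DR3b
CCCTCTACTCGCTAGAGAAATTAATTGAATGGAAAC
>DR4
CCTTACCTATTAGGTCAAATAGGATTAGTTGGAAAC
>DR4a
GTTTCCAACTAATCCTATTTGACCTAATAGGTAAGG
>DR4c
CTTACCTATTAGGTCAAATAGGATTAGTTGGAAAC
>DR5
CTTTTAACTTCTTAGCAAGTTTAATTAATGGAAAC
>DR5a
GTTTCCATTAATTAAACTTGCTAAGAAGTTAAAAG
>DR6
CTTTCATCTCTTACTCCCCGCAAGGGGACGGAAAC
>DR7
GTGATCAACGCCTTACGGCATCAAAGGTTAGTACAC
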