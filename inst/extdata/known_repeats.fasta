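>AhydrL30
ATTTCAATACATCTAATGTTATTAATCAAC
>AlactL29
AGGATCATCCCCGCTTGTGCGGGTACAAC
>BcoprL32
GTCGCACCCTGCGTGGGTGCGTGGATTGAAAC
>FalocL36
TTTGAGAGTAGTGTAATTTCATATGGTAGTCAAAC
>GhaemL36
GTTTGAGAGATATGTAAATTTTGAATTCTACAAAAC
>LcrisL29
AGGATCACCTCCACATACGTGGAGAATAC
>LjassL36
GTTTTAGATGGTTGTTAGATCAATAAGGTTTAGATC
>LjensL36
GTTTTAGAAGGTTGTTAAATCAGTAAGTTGAAAAAC
>Neis_t014_L28
GTTACCTGCCGCACAGGCAGCTTAGAAA
>Neis_t014_L36
GTTGTAGCTCCCTTTCTCATTTCGCAGTGCTACAAT
>PacneL29
GTATTCCCCGCCTATGCGGGGGTGAGCCC
>PpropL29
CGGTTCATCCCCGCGCATGCGGGGAACAC
>SmutaL36
GTTTTAGAGCTGTGTTGTTTCGAATGGTTCCAAAAC
>SRS012279L38
TATAAAAGAAGAGAATCCAGTAGAATAAGGATTGAAAC
>SRS018394L37
GTATTGAAGGTCATCCATTTATAACAAGGTTTAAAAC
>SRS023604L36
GTTTGAGAGTAGTGTAATTTATGAAGGTACTAAAAC
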