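# Synthetic barcode-block whitelist (96 entries, 6 nt, pairwise Hamming distance >= 2).
# Generated sequences for testing and examples -- NOT the vendor SureCell list.
AAAACT
CCATGT
GTAACT
CCGGAA
GTAGAA
TCTTGC
ACTCGG
CCTTTC
CATATC
TCGTGA
TGCACG
CCCTAA
AGTACA
ATTAGG
ATATTC
ATCCCT
ACACTG
TATATG
CCGAAC
GTTCTA
ATAAAC
GACTTA
GCAACA
AGTCGC
AGGTAC
CGCTGG
ACGCCT
CCCGCT
TGCCGT
CTTCAA
GACCCT
CGTGCA
TCACAA
AGCCTC
AAGCCG
GAGTCT
AGGCTT
TGAAAC
AGCTGA
CGTGTG
AATACG
TGAGTC
GTCGGA
TTGAAT
ATCTAA
CGACCC
CTGCGC
AAGGAC
GTCGCC
CTTGAG
AGCACT
CCAGTC
CAGGCG
CCACGA
CGATAC
GACTCG
GCTAGC
AAACGC
GCGGTT
TATCTA
TGCAGC
TAATAT
CCTTAG
TAGTCG
GAGATG
ACCGGT
CATCAG
GCGGCA
TCCGAC
CCTACA
TGCTAC
CGGACC
ATGCGA
CTCGAA
AGACCT
CGTAAT
AGCCGG
GCCATG
TAACAC
TGATGT
CTCCGG
GCAGCT
CATGAC
GAGCAC
CGAGAG
TTCCTG
TTAGTT
GGAACG
CTATCG
AGCGCG
TAAGCG
CCAACC
CGCATT
TACGAA
GTACCC
ATCGTA
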