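>ref01
AGGATAACATTTGCAAGCGAGGTATCCGATCTGAGATTGAGATCCAGCCCCAAATTTAGAGAAGACGCCTGTGTCCTCAGTCTGAGGACGCACTATACTCTTGACCTGGTGCACGTCGCA
>ref02
AGGATAACATTTGCAAGCGCGGTATCCGATCTGCGATTGAGATGCAGCCCCAAATTTAGAGAAGACCCCGGTGTCCTCAGTCTGAGGACGCACTAAACTCTTGACCTGGTGCACGTCGCA
>ref03
AGGATAACATTTGCAAGCGCGGTATCCTATCTGAGATTGAGATGCAGCCCCAAATTTAGAGAAGACCCCTGTGTCCTCAGTCTGAGGACGCACTAAACTCTTGACCTGGTGCACGTCGCA
>ref04
AGGATAACATTTGCAACCGAGTTATCCGATCTGAGATTGAGATCCAGCCCCAAATTTAGAGAAGACCCCTGTGTCCTCAGTCTGCGGACGCACTAAACTCTTGACCTGGTGCACGTCGCA
>ref05
AGGATGACATTTGCAAGCGCGGTATCCCATCTGAGATTGAGATGCAGCCCCAAATTTAGAGAAGACCCCTGTGTCCTCAGTCTGAGGACGCACTAAACTCTTGACCTGGCGCACGTCGCA
>ref06
AGGATAACATTTGCAAGCGCGGTATCCGATCAGAGATTGAGATGCATACCCAAATTTAGAGAAGACCCCTGTGTCCTCAGTCTGAGGACGCACTAAACTCTTGACCTGGTACACGTCGCA
>ref07
AGGATAAGATTTGCAAGCGCGGTATCCGATCTGAGATTGAGATGCAGCCCCAAATTTAGAGAAGACCCCTGTGTCCTCAGTCTGAGGACGCACTAAACTCTTTACCTGGTGCACGTCGCA
>ref08
AGGATAACATTAGCTAGCGCGGTATCCGATCTGAGATTTAGATGCAGCCCCAAATTTAGAGAAGACCCCGGTGTCCTCAGTCTGAGGACGCACTAACCTCTTCACCTGGTGCACGTCGCA
>ref09
AGGATAACATTTGCAAGCGCGGTATCCGATCTGAGATTGAGATGCAGCCCCAAATTTACAGAAGACCCCGGTGTCCTCAGTCTGCGGACGCACTAAACTCTTGACCAGGTGCACGTCGCA
>ref10
AGGATAACATTTGCAAGCGCGGTATCCGATCTGAGATTGAGATGCAGCCCCAAATTTAGACAAAACCCCTGTGTCCTCAGTCTGAGGACGCACTAAACTCTTGACCTGGTGCACGTCGCA
>ERVK7_5LTR
AGGATAACATTTGCAAGCGCGGTATCCGATCTGAGATTGAGATGCAGCCCCAAATTCAGAGAAGACCCCTGTGTCCTCAGTCTGAGGACGCACTAAACTCTTGACCTGGTGCACGTCGCA
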