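>rno-let-7c-5p synthetic stand-in mature sequence (rat); seed nt2-8 conserved vs hsa
UGAGGUAGUAGGUUGUAUGGUU
>hsa-let-7c-5p synthetic stand-in mature sequence (human)
UGAGGUAGUAGGUUGUAUGGUU
>rno-miR-132-3p synthetic stand-in; seed conserved
UAACAGUCUACAGCCAUGGUCG
>hsa-miR-132-3p synthetic stand-in
UAACAGUCUACAGCCAUGGUCG
>rno-miR-155-5p synthetic stand-in; differs from hsa outside the seed (position 12)
UUAAUGCUAAUUGUGAUAGGGGU
>hsa-miR-155-5p synthetic stand-in
UUAAUGCUAAUCGUGAUAGGGGU
>rno-miR-665 synthetic stand-in; differs from hsa outside the seed (position 16)
ACCAGGAGGCUGAGGUCCCU
>hsa-miR-665 synthetic stand-in
ACCAGGAGGCUGAGGCCCCU
>rno-miR-130b-3p synthetic stand-in; seed conserved; wrapped lines
CAGUGCAAUGAUGA
AAGGGCAU
>hsa-miR-130b-3p synthetic stand-in
CAGUGCAAUGAUGAAAGGGCAU
>rno-miR-223-3p synthetic stand-in; RNA alphabet
UGUCAGUUUGUCAAAUACCCCA
>hsa-miR-223-3p synthetic stand-in; DNA alphabet, conserved after U/T unification
TGTCAGTTTGTCAAATACCCCA
>rno-miR-496-3p synthetic stand-in; seed NOT conserved (mismatch at position 4)
UGAGUAUUACAUGGCCAAUCUC
>hsa-miR-496-3p synthetic stand-in
UGACUAUUACAUGGCCAAUCUC
>rno-miR-21-3p synthetic stand-in; seed NOT conserved (mismatch at position 6)
CAACACCAGUCGAUGGGCUGU
>hsa-miR-21-3p synthetic stand-in
CAACAGCAGUCGAUGGGCUGU
>rno-miR-361-3p synthetic stand-in; seed NOT conserved (one-nucleotide register shift)
UCCCCCAGGUGUGAUUCUGAUUU
>hsa-miR-361-3p synthetic stand-in
CCCCCAGGUGUGAUUCUGAUUUG
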