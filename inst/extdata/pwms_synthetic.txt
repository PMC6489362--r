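# Synthetic position count matrices for four liver-relevant TFs.
# These are NOT the JASPAR motifs for these factors. Each motif has one
# dominant position (97:1:1:1) and moderately informative flanking
# positions (70:10:10:10), so that disrupting the dominant base shifts
# the normalized match score by more than 0.3 while shifted placements
# cannot recover a high score by chance.
>SYN_EGR1 EGR1
A [ 10  1 10 10 10 10 ]
C [ 10 97 10 10 70 10 ]
G [ 70  1 70 70 10 70 ]
T [ 10  1 10 10 10 10 ]
>SYN_CTCF CTCF
A [ 10 10 97 10 10 10 ]
C [ 70 70  1 10 10 10 ]
G [ 10 10  1 70 70 10 ]
T [ 10 10  1 10 10 70 ]
>SYN_KLF5 KLF5
A [ 10  1 10 10 10 ]
C [ 10  1 10 70 10 ]
G [ 70 97 70 10 70 ]
T [ 10  1 10 10 10 ]
>SYN_HINFP HINFP
A [ 10 10 10  1 70 ]
C [ 70 10 10 97 10 ]
G [ 10 70 10  1 10 ]
T [ 10 10 70  1 10 ]
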