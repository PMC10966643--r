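REMARK synthetic 6-atom pocket fixture (hand-countable: 3 C, 2 N, 1 O)
ATOM      1  C   UNK A   1       4.000   0.000   0.000  1.00  0.00           C
ATOM      2  C   UNK A   1       0.000   4.500   0.000  1.00  0.00           C
ATOM      3  N   UNK A   1       0.000   0.000   5.000  1.00  0.00           N
ATOM      4  O   UNK A   1      -4.200   0.000   0.000  1.00  0.00           O
ATOM      5  N   UNK A   1       0.000  -4.800   0.000  1.00  0.00           N
ATOM      6  C   UNK A   1       3.000   3.000   3.000  1.00  0.00           C
HETATM    7  O   HOH A   2      20.000  20.000  20.000  1.00  0.00           O
END
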