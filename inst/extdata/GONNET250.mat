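# Gonnet PAM250-equivalent substitution matrix (Gonnet, Cohen & Benner 1992),
# entries multiplied by 10 and rounded to integers so dynamic programming is
# integer-exact. X is scored 0 against every residue.
# Format: first non-comment line = residue alphabet; each following line =
# residue letter followed by its full row of integer scores.
A R N D C Q E G H I L K M F P S T W Y V X
A 24 -6 -3 -3 5 -2 0 5 -8 -8 -12 -4 -7 -23 3 11 6 -36 -22 1 0
R -6 47 3 -3 -22 15 4 -10 6 -24 -22 27 -17 -32 -9 -2 -2 -16 -18 -20 0
N -3 3 38 22 -18 7 9 4 12 -28 -30 8 -22 -31 -9 9 5 -36 -14 -22 0
D -3 -3 22 47 -32 9 27 1 4 -38 -40 5 -30 -45 -7 5 0 -52 -28 -29 0
C 5 -22 -18 -32 115 -24 -30 -20 -13 -11 -15 -28 -9 -8 -31 1 -5 -10 -5 0 0
Q -2 15 7 9 -24 27 17 -10 12 -19 -16 15 -10 -26 -2 2 0 -27 -17 -15 0
E 0 4 9 27 -30 17 36 -8 4 -27 -28 12 -20 -39 -5 2 -1 -43 -27 -19 0
G 5 -10 4 1 -20 -10 -8 66 -14 -45 -44 -11 -35 -52 -16 4 -11 -40 -40 -33 0
H -8 6 12 4 -13 12 4 -14 60 -22 -19 6 -13 -1 -11 -2 -3 -8 22 -20 0
I -8 -24 -28 -38 -11 -19 -27 -45 -22 40 28 -21 25 10 -26 -18 -6 -18 -7 31 0
L -12 -22 -30 -40 -15 -16 -28 -44 -19 28 40 -21 28 20 -23 -21 -13 -7 0 18 0
K -4 27 8 5 -28 15 12 -11 6 -21 -21 32 -14 -33 -6 1 1 -35 -21 -17 0
M -7 -17 -22 -30 -9 -10 -20 -35 -13 25 28 -14 43 16 -24 -14 -6 -10 -2 16 0
F -23 -32 -31 -45 -8 -26 -39 -52 -1 10 20 -33 16 70 -38 -28 -22 36 51 1 0
P 3 -9 -9 -7 -31 -2 -5 -16 -11 -26 -23 -6 -24 -38 76 4 1 -50 -31 -18 0
S 11 -2 9 5 1 2 2 4 -2 -18 -21 1 -14 -28 4 22 15 -33 -19 -10 0
T 6 -2 5 0 -5 0 -1 -11 -3 -6 -13 1 -6 -22 1 15 25 -35 -19 0 0
W -36 -16 -36 -52 -10 -27 -43 -40 -8 -18 -7 -35 -10 36 -50 -33 -35 142 41 -26 0
Y -22 -18 -14 -28 -5 -17 -27 -40 22 -7 0 -21 -2 51 -31 -19 -19 41 78 -11 0
V 1 -20 -22 -29 0 -15 -19 -33 -20 31 18 -17 16 1 -18 -10 0 -26 -11 34 0
X 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
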