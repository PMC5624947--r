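# SYNTHETIC transmembrane-adapted substitution table (stand-in).
# This is NOT the published PHAT(75/73) matrix. It is a deterministic
# BLOSUM62-derived construction used as the packaged default for scoring
# transmembrane helix blocks: distinct pairs within the apolar helix core set
# {I,L,V,M,F,A} score +1 relative to BLOSUM62 (conservative exchanges inside
# the bilayer are common), and cross pairs between the polar/charged set
# {D,E,K,R,N,Q,H} and the hydrophobic set {I,L,V,M,F,A,W,Y,C} score -1
# (such exchanges are rare inside the membrane). Diagonal unchanged; X = 0.
# Users holding the published PHAT table can load it via read_score_matrix().
# Format: first non-comment line = residue alphabet; each following line =
# residue letter followed by its full row of integer scores.
A R N D C Q E G H I L K M F P S T W Y V X
A 4 -2 -3 -3 0 -2 -2 0 -3 0 0 -2 0 -1 -1 1 0 -3 -2 1 0
R -2 5 0 -2 -4 1 0 -2 0 -4 -3 2 -2 -4 -2 -1 -1 -4 -3 -4 0
N -3 0 6 1 -4 0 0 0 1 -4 -4 0 -3 -4 -2 1 0 -5 -3 -4 0
D -3 -2 1 6 -4 0 2 -1 -1 -4 -5 -1 -4 -4 -1 0 -1 -5 -4 -4 0
C 0 -4 -4 -4 9 -4 -5 -3 -4 -1 -1 -4 -1 -2 -3 -1 -1 -2 -2 -1 0
Q -2 1 0 0 -4 5 2 -2 0 -4 -3 1 -1 -4 -1 0 -1 -3 -2 -3 0
E -2 0 0 2 -5 2 5 -2 0 -4 -4 1 -3 -4 -1 0 -1 -4 -3 -3 0
G 0 -2 0 -1 -3 -2 -2 6 -2 -4 -4 -2 -3 -3 -2 0 -2 -2 -3 -3 0
H -3 0 1 -1 -4 0 0 -2 8 -4 -4 -1 -3 -2 -2 -1 -2 -3 1 -4 0
I 0 -4 -4 -4 -1 -4 -4 -4 -4 4 3 -4 2 1 -3 -2 -1 -3 -1 4 0
L 0 -3 -4 -5 -1 -3 -4 -4 -4 3 4 -3 3 1 -3 -2 -1 -2 -1 2 0
K -2 2 0 -1 -4 1 1 -2 -1 -4 -3 5 -2 -4 -1 0 -1 -4 -3 -3 0
M 0 -2 -3 -4 -1 -1 -3 -3 -3 2 3 -2 5 1 -2 -1 -1 -1 -1 2 0
F -1 -4 -4 -4 -2 -4 -4 -3 -2 1 1 -4 1 6 -4 -2 -2 1 3 0 0
P -1 -2 -2 -1 -3 -1 -1 -2 -2 -3 -3 -1 -2 -4 7 -1 -1 -4 -3 -2 0
S 1 -1 1 0 -1 0 0 0 -1 -2 -2 0 -1 -2 -1 4 1 -3 -2 -2 0
T 0 -1 0 -1 -1 -1 -1 -2 -2 -1 -1 -1 -1 -2 -1 1 5 -2 -2 0 0
W -3 -4 -5 -5 -2 -3 -4 -2 -3 -3 -2 -4 -1 1 -4 -3 -2 11 2 -3 0
Y -2 -3 -3 -4 -2 -2 -3 -3 1 -1 -1 -3 -1 3 -3 -2 -2 2 7 -1 0
V 1 -4 -4 -4 -1 -3 -3 -3 -4 4 2 -3 2 0 -2 -2 0 -3 -1 4 0
X 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
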