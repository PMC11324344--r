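 A C D E F G H I K L M N P Q R S T V W Y
A -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
C -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
D 0.00 0.00 0.60 0.60 0.00 0.00 -0.30 0.00 -0.60 0.00 0.00 0.00 0.00 0.00 -0.60 0.00 0.00 0.00 0.00 0.00
E 0.00 0.00 0.60 0.60 0.00 0.00 -0.30 0.00 -0.60 0.00 0.00 0.00 0.00 0.00 -0.60 0.00 0.00 0.00 0.00 0.00
F -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
G 0.10 0.10 0.00 0.00 0.10 -0.20 0.00 0.10 0.00 0.10 0.10 -0.20 -0.20 -0.20 0.00 -0.20 -0.20 0.10 0.10 -0.20
H 0.00 0.00 -0.30 -0.30 0.00 0.00 0.15 0.00 0.30 0.00 0.00 0.00 0.00 0.00 0.30 0.00 0.00 0.00 0.00 0.00
I -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
K 0.00 0.00 -0.60 -0.60 0.00 0.00 0.30 0.00 0.60 0.00 0.00 0.00 0.00 0.00 0.60 0.00 0.00 0.00 0.00 0.00
L -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
M -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
N 0.10 0.10 0.00 0.00 0.10 -0.20 0.00 0.10 0.00 0.10 0.10 -0.20 -0.20 -0.20 0.00 -0.20 -0.20 0.10 0.10 -0.20
P 0.10 0.10 0.00 0.00 0.10 -0.20 0.00 0.10 0.00 0.10 0.10 -0.20 -0.20 -0.20 0.00 -0.20 -0.20 0.10 0.10 -0.20
Q 0.10 0.10 0.00 0.00 0.10 -0.20 0.00 0.10 0.00 0.10 0.10 -0.20 -0.20 -0.20 0.00 -0.20 -0.20 0.10 0.10 -0.20
R 0.00 0.00 -0.60 -0.60 0.00 0.00 0.30 0.00 0.60 0.00 0.00 0.00 0.00 0.00 0.60 0.00 0.00 0.00 0.00 0.00
S 0.10 0.10 0.00 0.00 0.10 -0.20 0.00 0.10 0.00 0.10 0.10 -0.20 -0.20 -0.20 0.00 -0.20 -0.20 0.10 0.10 -0.20
T 0.10 0.10 0.00 0.00 0.10 -0.20 0.00 0.10 0.00 0.10 0.10 -0.20 -0.20 -0.20 0.00 -0.20 -0.20 0.10 0.10 -0.20
V -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
W -0.50 -0.50 0.00 0.00 -0.50 0.10 0.00 -0.50 0.00 -0.50 -0.50 0.10 0.10 0.10 0.00 0.10 0.10 -0.50 -0.50 0.10
Y 0.10 0.10 0.00 0.00 0.10 -0.20 0.00 0.10 0.00 0.10 0.10 -0.20 -0.20 -0.20 0.00 -0.20 -0.20 0.10 0.10 -0.20
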