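word	class
G2P	nuclear
G11P	nuclear
G8P	nuclear
P11P	nuclear
P5P	nuclear
P3Q	nuclear
P5Q	nuclear
K1K	nuclear
K6K	nuclear
K10K	nuclear
K2K	nuclear
K5K	nuclear
K0K	nuclear
K3K	nuclear
K4K	nuclear
E4E	nuclear
E1E	nuclear
E8E	nuclear
E0E	nuclear
P1T	nuclear
P0T	nuclear
P6T	nuclear
P10T	nuclear
G2G	nuclear
G1G	nuclear
G5G	nuclear
P1S	nuclear
S6P	nuclear
P3G	nuclear
G4P	nuclear
P0G	nuclear
Q11Q	nuclear
Q10Q	nuclear
Q5Q	nuclear
R13R	nuclear
R11R	nuclear
R10R	nuclear
R9R	nuclear
R12R	nuclear
R7R	nuclear
R3R	nuclear
R4R	nuclear
C8S	nuclear
S2C	nuclear
S6C	nuclear
N6P	nuclear
P12N	nuclear
S9D	nuclear
E12D	nuclear
D12D	nuclear
D4D	nuclear
D13D	nuclear
S12T	nuclear
S8T	nuclear
S10T	nuclear
K0R	nuclear
K2R	nuclear
R2R	nuclear
R0R	nuclear
R0K	nuclear
R2K	nuclear
K1R	nuclear
R1K	nuclear
R3K	nuclear
K4R	nuclear
M3P	nuclear
P12M	nuclear
R1H	nuclear
Q8R	nuclear
Q2H	nuclear
H0R	nuclear
S7Q	nuclear
Q12S	nuclear
S13H	nuclear
S10H	nuclear
S2H	nuclear
H6S	nuclear
S12H	nuclear
P7Y	nuclear
P4Y	nuclear
Y5P	nuclear
N3N	nuclear
N6N	nuclear
N0N	nuclear
K1H	nuclear
H0K	nuclear
H6K	nuclear
K10H	nuclear
D2S	nuclear
D5S	nuclear
K8S	nuclear
D0S	nuclear
N8N	nuclear
H8N	nuclear
H5N	nuclear
S6L	nuclear
T4E	nuclear
E13S	nuclear
T6E	nuclear
S13S	nuclear
S10S	nuclear
H0H	nuclear
H4H	nuclear
H1H	nuclear
H13H	nuclear
N0E	nuclear
N0K	nuclear
N4K	nuclear
K1N	nuclear
D2T	nuclear
G6L	nuclear
G8L	nuclear
E8C	nuclear
K1C	nuclear
K5C	nuclear
K7C	nuclear
C2C	nuclear
C0C	nuclear
K3C	nuclear
C4K	nuclear
H8C	nuclear
H12C	nuclear
H13C	nuclear
H10C	nuclear
D6I	nuclear
D10I	nuclear
D12I	nuclear
A13Q	nuclear
A6Q	nuclear
Q9A	nuclear
Q6A	nuclear
S11S	nuclear
M3S	nuclear
Q13T	nuclear
K9T	nuclear
Q1T	nuclear
Q9T	nuclear
N1S	nuclear
S7N	nuclear
N8S	nuclear
H1I	nuclear
I0H	nuclear
E12I	nuclear
S2E	nuclear
E11I	nuclear
D6A	nuclear
S3D	nuclear
D8A	nuclear
M13Q	nuclear
M3Q	nuclear
L13S	nuclear
L12S	nuclear
V6S	nuclear
S9N	nuclear
S13G	nuclear
E9S	nuclear
S3S	nuclear
N0S	nuclear
S3N	nuclear
H1Q	nuclear
H10Q	nuclear
H3Q	nuclear
H5Q	nuclear
T7E	nuclear
T8E	nuclear
T12E	nuclear
T9E	nuclear
W13K	nuclear
W11K	nuclear
N11I	nuclear
I12N	nuclear
M13D	nuclear
M2D	nuclear
F13D	nuclear
L1H	nuclear
H1L	nuclear
A3H	nuclear
L5H	nuclear
R0G	nuclear
A9H	nuclear
H10A	nuclear
P3R	nuclear
A10H	nuclear
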