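>SYN0001.1 HDX1
A [ 1 97 97 1 1 97 1 1 1 97 97 1 ]
C [ 1 1 1 1 1 1 1 97 1 1 1 1 ]
G [ 1 1 1 1 1 1 97 1 1 1 1 1 ]
T [ 97 1 1 97 97 1 1 1 97 1 1 97 ]
>SYN0002.1 HDX2
A [ 1 1 97 97 1 1 1 1 ]
C [ 97 1 1 1 1 1 1 1 ]
G [ 1 1 1 1 1 1 97 97 ]
T [ 1 97 1 1 97 97 1 1 ]
>SYN0003.1 HDX3
A [ 15 55 55 15 15 15 ]
C [ 15 15 15 15 15 55 ]
G [ 15 15 15 15 55 15 ]
T [ 55 15 15 55 15 15 ]
>SYN0004.1 HDX4
A [ 55 15 15 55 15 ]
C [ 15 15 15 15 15 ]
G [ 15 15 15 15 55 ]
T [ 15 55 55 15 15 ]
>SYN0005.1 HDX5
A [ 15 55 55 15 15 15 ]
C [ 15 15 15 15 55 55 ]
G [ 15 15 15 15 15 15 ]
T [ 55 15 15 55 15 15 ]
>SYN0006.1 HDX6
A [ 15 15 55 55 15 15 ]
C [ 15 15 15 15 15 15 ]
G [ 55 15 15 15 15 15 ]
T [ 15 55 15 15 55 55 ]
>SYN0007.1 ZNF1
A [ 1 1 1 1 1 1 1 1 1 1 ]
C [ 1 1 1 1 97 1 1 1 1 97 ]
G [ 97 97 97 97 1 97 97 97 97 1 ]
T [ 1 1 1 1 1 1 1 1 1 1 ]
>SYN0008.1 ZNF2
A [ 1 1 1 1 97 1 1 1 ]
C [ 1 97 1 97 1 1 1 97 ]
G [ 97 1 97 1 1 1 97 1 ]
T [ 1 1 1 1 1 97 1 1 ]
>SYN0009.1 ZNF3
A [ 15 15 15 15 15 ]
C [ 15 15 15 55 15 ]
G [ 55 55 55 15 55 ]
T [ 15 15 15 15 15 ]
>SYN0010.1 ZNF4
A [ 15 15 15 15 15 ]
C [ 15 55 55 55 55 ]
G [ 55 15 15 15 15 ]
T [ 15 15 15 15 15 ]
>SYN0011.1 ZNF5
A [ 15 15 15 15 15 ]
C [ 55 15 55 55 55 ]
G [ 15 55 15 15 15 ]
T [ 15 15 15 15 15 ]
>SYN0012.1 ZNF6
A [ 15 15 15 15 15 55 ]
C [ 15 15 55 15 15 15 ]
G [ 55 55 15 55 55 15 ]
T [ 15 15 15 15 15 15 ]
>SYN0013.1 FOX1
A [ 1 1 97 97 97 1 97 97 97 1 ]
C [ 1 1 1 1 1 97 1 1 1 97 ]
G [ 97 1 1 1 1 1 1 1 1 1 ]
T [ 1 97 1 1 1 1 1 1 1 1 ]
>SYN0014.1 FOX2
A [ 15 15 15 15 15 55 15 ]
C [ 15 15 15 15 15 15 55 ]
G [ 15 55 15 15 15 15 15 ]
T [ 55 15 55 55 55 15 15 ]
>SYN0015.1 FOX3
A [ 55 55 55 15 55 ]
C [ 15 15 15 55 15 ]
G [ 15 15 15 15 15 ]
T [ 15 15 15 15 15 ]
>SYN0016.1 FOX4
A [ 15 15 15 15 15 15 ]
C [ 15 15 15 15 15 15 ]
G [ 15 55 15 15 55 15 ]
T [ 55 15 55 55 15 55 ]
>SYN0017.1 BHL1
A [ 1 97 1 1 1 1 97 1 ]
C [ 97 1 97 1 1 1 1 97 ]
G [ 1 1 1 97 1 97 1 1 ]
T [ 1 1 1 1 97 1 1 1 ]
>SYN0018.1 BHL2
A [ 15 55 15 15 15 15 ]
C [ 55 15 15 55 15 15 ]
G [ 15 15 55 15 15 55 ]
T [ 15 15 15 15 55 15 ]
>SYN0019.1 BHL3
A [ 15 55 15 15 15 15 ]
C [ 55 15 55 55 15 15 ]
G [ 15 15 15 15 15 55 ]
T [ 15 15 15 15 55 15 ]
>SYN0020.1 BHL4
A [ 15 55 15 15 15 ]
C [ 55 15 15 15 15 ]
G [ 15 15 15 55 15 ]
T [ 15 15 55 15 55 ]
>SYN0021.1 BZP1
A [ 1 1 97 1 1 1 97 1 1 97 ]
C [ 1 1 1 97 1 97 1 1 97 1 ]
G [ 1 97 1 1 1 1 1 97 1 1 ]
T [ 97 1 1 1 97 1 1 1 1 1 ]
>SYN0022.1 BZP2
A [ 15 15 55 15 15 15 ]
C [ 15 15 15 55 15 15 ]
G [ 15 55 15 15 55 15 ]
T [ 55 15 15 15 15 55 ]
>SYN0023.1 BZP3
A [ 15 55 15 15 15 ]
C [ 15 15 55 15 55 ]
G [ 55 15 15 15 15 ]
T [ 15 15 15 55 15 ]
>SYN0024.1 BZP4
A [ 55 15 15 15 15 55 ]
C [ 15 55 15 15 55 15 ]
G [ 15 15 55 15 15 15 ]
T [ 15 15 15 55 15 15 ]
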