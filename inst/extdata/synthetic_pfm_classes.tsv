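matrix_id	tf_class
SYN0001.1	Homeo domain factors
SYN0002.1	Homeo domain factors
SYN0003.1	Homeo domain factors
SYN0004.1	Homeo domain factors
SYN0005.1	Homeo domain factors
SYN0006.1	Homeo domain factors
SYN0007.1	C2H2 zinc finger factors
SYN0008.1	C2H2 zinc finger factors
SYN0009.1	C2H2 zinc finger factors
SYN0010.1	C2H2 zinc finger factors
SYN0011.1	C2H2 zinc finger factors
SYN0012.1	C2H2 zinc finger factors
SYN0013.1	Fork head/winged helix factors
SYN0014.1	Fork head/winged helix factors
SYN0015.1	Fork head/winged helix factors
SYN0016.1	Fork head/winged helix factors
SYN0017.1	Basic helix-loop-helix factors
SYN0018.1	Basic helix-loop-helix factors
SYN0019.1	Basic helix-loop-helix factors
SYN0020.1	Basic helix-loop-helix factors
SYN0021.1	Basic leucine zipper factors
SYN0022.1	Basic leucine zipper factors
SYN0023.1	Basic leucine zipper factors
SYN0024.1	Basic leucine zipper factors
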