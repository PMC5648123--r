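name	sequence	class
CpG-1	AACGTT	stimulatory
CpG-2	GACGTT	stimulatory
CpG-3	AGCGTT	stimulatory
CpG-4	GTCGTT	stimulatory
CpG-5	AACGCT	stimulatory
TTAGGG	TTAGGG	suppressive
TCAAGCTTGA	TCAAGCTTGA	suppressive
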