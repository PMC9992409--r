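class_name	pattern	note
TRG_NLS_Bipartite_1	[KR]{2}.{7,15}[KR]{3}	bipartite: basic doublet, 7-15 residue linker, basic triplet
TRG_NLS_MonoCore_2	(?<![DE])K[KR].[KR](?![DE])	monopartite core K(K/R)x(K/R) with acidic-residue exclusion on both flanks
TRG_NLS_MonoExtC_3	K[KR].[KR].{0,2}[KR]	monopartite core with a C-terminal basic extension
TRG_NLS_MonoExtN_4	[KR].{0,2}K[KR].[KR]	monopartite core with an N-terminal basic extension
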