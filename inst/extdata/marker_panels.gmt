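type_I_fibre	cell-type markers for bulk human skeletal muscle	MYH7	TNNT1
type_II_fibre	cell-type markers for bulk human skeletal muscle	MYH1	MYH2	ATP2A1	TNNT3
satellite_cell	cell-type markers for bulk human skeletal muscle	PAX7	MYF5
endothelial	cell-type markers for bulk human skeletal muscle	ENG	TIE1	PECAM1	APLNR
pericyte	cell-type markers for bulk human skeletal muscle	RGS5	HIGD1B
macrophage	cell-type markers for bulk human skeletal muscle	F13A1	SPP1
T_cell	cell-type markers for bulk human skeletal muscle	CD3D	IL7R
B_cell	cell-type markers for bulk human skeletal muscle	MS4A1	CD79A
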