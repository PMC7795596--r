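raw	canonical
B cells naive	B_cells_naive
B cells memory	B_cells_memory
Plasma cells	Plasma_cells
T cells CD8	T_cells_CD8
T.cells.CD8	T_cells_CD8
T cells CD4 naive	T_cells_CD4_naive
T cells CD4 memory resting	T_cells_CD4_memory_resting
T cells CD4 memory activated	T_cells_CD4_memory_activated
T cells follicular helper	T_cells_follicular_helper
T cells regulatory (Tregs)	T_cells_regulatory_Tregs
T cells gamma delta	T_cells_gamma_delta
NK cells resting	NK_cells_resting
NK cells activated	NK_cells_activated
Monocytes	Monocytes
Macrophages M0	Macrophages_M0
Macrophages M1	Macrophages_M1
Macrophages M2	Macrophages_M2
Dendritic cells resting	Dendritic_cells_resting
Dendritic cells activated	Dendritic_cells_activated
Mast cells resting	Mast_cells_resting
Mast cells activated	Mast_cells_activated
Eosinophils	Eosinophils
Neutrophils	Neutrophils
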