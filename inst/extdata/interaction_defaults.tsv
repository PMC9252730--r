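# Default distance windows (Angstrom) for non-covalent interaction
# detection. Interactions are emitted for heavy-atom pairs in different
# residues whose classes satisfy the type's requirement and whose
# Euclidean distance lies in [d_min, d_max].
type	d_min	d_max
aromatic_stacking	1.5	3.5
disulfide_bridge	1.8	2.8
hydrogen_bond	2.0	3.9
hydrophobic	2.0	4.5
repulsive	2.0	6.0
salt_bridge	2.0	6.0
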