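# Single-nucleotide dangling-end stacking Gibbs energies, dG37 in kcal/mol,
# applied once per exposed terminus of the DNA/mRNA hybrid.  Values follow the
# DNA nearest-neighbour dangling-end convention (order of magnitude of the
# published 37C sets; mean approximately -0.45 kcal/mol = -0.7 kBT).
# end = 5p: the FIRST base of the doublet is the unpaired (dangling) base,
#           stacked on the 5' side of the terminal basepair.
# end = 3p: the SECOND base of the doublet is the unpaired base, stacked on
#           the 3' side of the terminal basepair.
# Doublets are written 5'->3' on the coding strand.
doublet	end	dG_kcal_mol
AA	5p	-0.51
AC	5p	-0.42
AG	5p	-0.62
AT	5p	-0.71
CA	5p	-0.96
CC	5p	-0.52
CG	5p	-0.72
CT	5p	-0.58
GA	5p	-0.58
GC	5p	-0.34
GG	5p	-0.56
GT	5p	-0.61
TA	5p	-0.51
TC	5p	-0.02
TG	5p	-0.13
TT	5p	-0.50
AA	3p	-0.12
AC	3p	-0.28
AG	3p	-0.01
AT	3p	-0.13
CA	3p	-0.82
CC	3p	-0.31
CG	3p	-0.01
CT	3p	-0.52
GA	3p	-0.92
GC	3p	-0.23
GG	3p	-0.44
GT	3p	-0.35
TA	3p	-0.48
TC	3p	-0.19
TG	3p	-0.50
TT	3p	-0.29
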