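# Nearest-neighbour standard Gibbs energies of RNA/DNA hybrid duplex
# propagation (Sugimoto 1995), dG37 in kcal/mol.  Doublet is the 5'->3'
# dinucleotide of the RNA strand written in DNA alphabet (U -> T); within the
# elongation complex this equals the coding (non-template) strand doublet.
# Initiation terms omitted (see DNA/DNA table note).
doublet	dG_kcal_mol
AA	-0.4
AC	-1.6
AG	-1.4
AT	-0.3
CA	-1.0
CC	-2.1
CG	-1.5
CT	-0.8
GA	-1.4
GC	-2.3
GG	-2.2
GT	-0.9
TA	-0.6
TC	-1.5
TG	-1.4
TT	-0.2
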