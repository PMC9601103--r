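# Synthetic example modules in the KEGG flat-file dialect.
# These are NOT real KEGG modules: they exercise every grammar feature
# (OR alternatives, complexes, optional subunits, a gap step).
ENTRY       MX0001
NAME        synthetic linear three-step module
DEFINITION  K11111 K11112 K11113
///
ENTRY       MX0002
NAME        synthetic module with alternative routes
DEFINITION  (K11121,K11122) K11123 (K11124,K11125 K11126)
///
ENTRY       MX0003
NAME        synthetic module with a complex and an optional subunit
DEFINITION  K11131+K11132-K11133 K11134
///
ENTRY       MX0004
NAME        synthetic module with a gap step
DEFINITION  K11141 -- K11142
///
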