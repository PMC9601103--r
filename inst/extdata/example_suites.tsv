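# Example gene-suite definitions (ANY-gene rule).
# The Ammonification Hydrolases EC families are the standard C-N-cleaving
# hydrolase/lyase classes (amine oxidoreductases EC 1.4.*, C-N hydrolases
# EC 3.5.*, ammonia-lyases EC 4.3.1.*). The DOM transporter suites below are
# SYNTHETIC placeholder KO lists (K5xxxx codes) standing in for a curated
# transporter gene catalogue; replace with your own suite file for real use.
suite_name	pattern
Ammonification Hydrolases	EC:1.4.*
Ammonification Hydrolases	EC:3.5.*
Ammonification Hydrolases	EC:4.3.1.*
Carboxylic Acids	K50001
Carboxylic Acids	K50002
Carboxylic Acids	K50003
Compatible Solutes	K50011
Compatible Solutes	K50012
Carbohydrate Pentoses	K50021
Carbohydrate Pentoses	K50022
General Carbohydrates	K50031
General Carbohydrates	K50032
General Carbohydrates	K50033
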