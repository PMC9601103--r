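# Example feature -> benefit-group mapping for the metabolism matrix.
# Metabolisms that supply the host (nitrogen acquisition, ammonification)
# sit in hosts_benefit; uptake of host-provisioned dissolved organic
# matter sits in microbes_benefit. Module ids MS0001.. refer to the
# synthetic example modules shipped alongside.
feature_name	benefit_group
Nitrogen Fixation (nifH+nifD)	hosts_benefit
Ammonification Hydrolases	hosts_benefit
Carboxylic Acids	microbes_benefit
Compatible Solutes	microbes_benefit
Carbohydrate Pentoses	microbes_benefit
General Carbohydrates	microbes_benefit
MS0001	hosts_benefit
MS0002	hosts_benefit
MS0003	hosts_benefit
MS0004	hosts_benefit
MS0005	hosts_benefit
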