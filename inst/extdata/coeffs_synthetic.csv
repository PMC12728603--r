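# SYNTHETIC coefficient table for tests and examples only.
# These numbers are arbitrary and do NOT reproduce any published transfer
# free-energy scale.
# provenance: synthetic test data
# columns: group,dg,a_ref
group,dg,a_ref
backbone,100,40
ALA,-25,70
GLY,10,30
SER,55,80
VAL,-40,110
LEU,-60,140
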