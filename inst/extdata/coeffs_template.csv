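# Template for an additive transfer-model coefficient table.
# group: "backbone" or a three-letter residue type covering every residue present.
# dg: group transfer free energy at 1 mol/L cosolvent, cal/mol per reference unit.
# a_ref: reference accessible area for the group, A^2 (> 0).
# Fill dg/a_ref from a published group-transfer compilation for your cosolvent
# (e.g. urea or TMAO scales) and record the source in this header: this package
# ships no published coefficient values.
# provenance: TEMPLATE - values below are placeholders (all dg = 0)
# columns: group,dg,a_ref
group,dg,a_ref
backbone,0,40
ALA,0,70
GLY,0,30
SER,0,80
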