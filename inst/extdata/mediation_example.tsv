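exposure	mediator	outcome	total_beta	beta_a	beta_b
class.Actinobacteria.id.419	basal_metabolic_rate	osteoarthritis	-0.007139	-0.0219	0.00845
order.Bifidobacteriales.id.432	basal_metabolic_rate	osteoarthritis	-0.006381	-0.0301	0.00845
family.Bifidobacteriaceae.id.433	basal_metabolic_rate	osteoarthritis	-0.006381	-0.0301	0.00845
class.Actinobacteria.id.419	basal_metabolic_rate	knee_osteoarthritis	-0.075545	-0.0219	0.56506
class.Actinobacteria.id.419	basal_metabolic_rate	hip_osteoarthritis	-0.113638	-0.0219	0.26678
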