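# Strong triadic closure: transitive-triad shares well above the default.
n_classrooms_rural: 3
n_classrooms_urban: 3
class_size_range: [18, 25]
p_female: 0.54
base_tie_prob: 0.15
reciprocity_boost: 0.35
homophily_boost: 0.10
closure_prob: 0.6
closure_sweeps: 3
intensity_cuts: [0.5, 0.8, 0.95]
risk_prevalence: 0.41
risk_setting_effect: 0.05
drink_tie_prob_both_risk: 0.60
drink_tie_prob_otherwise: 0.08
audit_threshold: 8
seed: 1
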