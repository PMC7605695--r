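# No reciprocity, homophily or closure effects; identical rural and urban
# conditions; nominations independent of risk status. Useful as a calibration
# baseline: setting contrasts should be null.
n_classrooms_rural: 3
n_classrooms_urban: 3
class_size_range: [18, 25]
p_female: 0.5
base_tie_prob: 0.15
reciprocity_boost: 0.0
homophily_boost: 0.0
closure_prob: 0.0
closure_sweeps: 0
intensity_cuts: [0.5, 0.8, 0.95]
risk_prevalence: 0.4
risk_setting_effect: 0.0
drink_tie_prob_both_risk: 0.20
drink_tie_prob_otherwise: 0.20
audit_threshold: 8
seed: 1
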