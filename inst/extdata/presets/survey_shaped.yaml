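# Shape of the original survey: 10 classrooms (6 rural totalling 100
# students, 4 urban totalling 95), 195 actors, p_female 0.54, rural risk
# prevalence above urban. No claim of matching the survey's unknown
# generating parameters.
n_classrooms_rural: 6
n_classrooms_urban: 4
class_sizes_rural: [17, 17, 17, 17, 16, 16]
class_sizes_urban: [24, 24, 24, 23]
p_female: 0.54
base_tie_prob: 0.15
reciprocity_boost: 0.35
homophily_boost: 0.10
closure_prob: 0.15
closure_sweeps: 2
intensity_cuts: [0.5, 0.8, 0.95]
risk_prevalence: 0.41
risk_setting_effect: 0.05
drink_tie_prob_both_risk: 0.60
drink_tie_prob_otherwise: 0.08
audit_threshold: 8
seed: 1
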