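# Five-state breast-cancer progression graph (preset) plus the covariate
# mapping used by the synthetic cohorts: tumour size and grade act on the
# three transitions out of surgery, size also on post-relapse progression
# and cancer death, and age (centred) only on transitions to other-cause
# death.
preset: figure1_breast5
covariate_map:
  size_surgery:
    covariate: size
    transitions: [1, 2, 3]
  grade_surgery:
    covariate: grade
    transitions: [1, 2, 3]
  size_relapse:
    covariate: size
    transitions: [5, 6, 8]
  age_death:
    covariate: agec
    transitions: [4, 7, 9]
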