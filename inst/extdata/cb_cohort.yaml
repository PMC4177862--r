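# Default study conditions for a congenitally blind (CB) vs normal sighted
# control (NC) corpus-callosum cohort: 28 subjects per group, 16 male and
# 12 female, matched for age. Region areas are midsagittal cross-sections in
# mm^2 (stereotaxic space); bending angles are in degrees. Splenium, isthmus
# and posterior mid-body distributions carry the group differences; anterior
# third and anterior mid-body show no group effect and share one
# distribution (their group values are not separately established; the
# defaults are realistic adult magnitudes chosen once).
groups:
  CB:
    "n": 28
    males: 16
    females: 12
    age_range: [19, 63]
    bending_angle: {mean: 109.6, sd: 4.9}
    base_mm: {mean: 100.0, sd: 3.0}
    regions:
      anterior_third: {mean: 300.0, sd: 40.0}
      anterior_midbody: {mean: 100.0, sd: 15.0}
      posterior_midbody: {mean: 107.26, sd: 21.67}
      isthmus: {mean: 79.4, sd: 16.66}
      splenium: {mean: 225.64, sd: 31.7}
  NC:
    "n": 28
    males: 16
    females: 12
    age_range: [21, 58]
    bending_angle: {mean: 113.4, sd: 5.7}
    base_mm: {mean: 100.0, sd: 3.0}
    regions:
      anterior_third: {mean: 300.0, sd: 40.0}
      anterior_midbody: {mean: 100.0, sd: 15.0}
      posterior_midbody: {mean: 89.64, sd: 16.51}
      isthmus: {mean: 64.16, sd: 10.31}
      splenium: {mean: 260.84, sd: 41.7}
# Group x sex cell distributions of the isthmus, for interaction-F
# simulations.
isthmus_cells:
  CB_M: {mean: 87.24, sd: 18.81, "n": 16}
  CB_F: {mean: 68.95, sd: 11.83, "n": 12}
  NC_M: {mean: 63.49, sd: 10.05, "n": 16}
  NC_F: {mean: 65.06, sd: 11.04, "n": 12}
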