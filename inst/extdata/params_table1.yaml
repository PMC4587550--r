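parameters:
  anc_access:
    soc:
      family: uniform
      min: 0.6
      max: 0.7
    kshi:
      family: uniform
      min: 0.8
      max: 0.9
  facility_all:
    soc:
      family: uniform
      min: 0.4
      max: 0.6
    kshi:
      family: uniform
      min: 0.65
      max: 0.7
  eoc_facility:
    soc:
      family: uniform
      min: 0.9
      max: 0.95
    kshi:
      family: point
      mean: 1.0
  facility_if_anc:
    shared:
      family: beta
      mean: 0.96
      sd: 0.03
  home_if_anc:
    shared:
      family: beta
      mean: 0.05
      sd: 0.03
  eoc_home:
    shared:
      family: beta
      mean: 0.136
      sd: 0.02
  p_pph:
    shared:
      family: beta
      mean: 0.051
      sd: 0.04
  p_anaemia_pph:
    shared:
      family: beta
      mean: 0.12
      sd: 0.01
  p_death_pph:
    shared:
      family: uniform
      min: 0.028
      max: 0.273
  rr_pph_death_eoc:
    shared:
      family: beta
      mean: 0.34
      sd: 0.19
  rr_anaemia_eoc:
    shared:
      family: beta
      mean: 0.5
      sd: 0.14
  p_sepsis:
    shared:
      family: triangular
      mean: 0.017
      min: 0.01
      max: 0.03
  p_infertility_sepsis:
    shared:
      family: uniform
      min: 0.05
      max: 0.1
  p_death_sepsis:
    shared:
      family: uniform
      min: 0.0
      max: 0.727
  rr_sepsis_facility:
    shared:
      family: triangular
      mean: 0.54
      min: 0.4
      max: 0.65
  p_ol:
    shared:
      family: beta
      mean: 0.06
      sd: 0.02
  p_fistula_ol:
    shared:
      family: beta
      mean: 0.14
      sd: 0.01
  p_death_ol:
    shared:
      family: beta
      mean: 0.007
      sd: 0.01
  p_htd:
    shared:
      family: beta
      mean: 0.085
      sd: 0.04
  p_death_htd:
    shared:
      family: beta
      mean: 0.083
      sd: 0.02
  rr_htd_anc:
    shared:
      family: beta
      mean: 0.41
      sd: 0.08
  cost_anc:
    shared:
      family: uniform
      min: 12.4
      max: 61.5
  cost_delivery_uncomp:
    shared:
      family: uniform
      min: 9.65
      max: 27.2
  cost_delivery_comp:
    shared:
      family: uniform
      min: 46.7
      max: 53.3
  cost_fistula:
    shared:
      family: uniform
      min: 190.9
      max: 382.7
  cost_anaemia:
    shared:
      family: uniform
      min: 9.81
      max: 13.79
  daly_death:
    shared:
      family: triangular
      mean: 23.43
      min: 21.09
      max: 25.77
  daly_anaemia:
    shared:
      family: triangular
      mean: 0.09
      min: 0.08
      max: 0.09
  daly_infertility:
    shared:
      family: triangular
      mean: 0.1
      min: 0.09
      max: 0.11
  daly_fistula:
    shared:
      family: triangular
      mean: 10.93
      min: 9.84
      max: 12.02
  discount_rate:
    shared:
      family: point
      mean: 0.03
  above_service_cost:
    shared:
      family: point
      mean: 24.1
  cohort_size:
    shared:
      family: point
      mean: 10000.0
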