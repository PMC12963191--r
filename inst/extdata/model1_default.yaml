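model_id: model1
layers:
  epidermis:
    thickness_mm: 0.1
    E_kPa: 1500.0
    nu: 0.48
    target_element_count: 40318.0
  dermis:
    thickness_mm: 1.5
    E_kPa: 35.0
    nu: 0.48
    target_element_count: 29802.0
  adipose:
    thickness_mm: 4.4
    E_kPa: 2.0
    nu: 0.48
    target_element_count: 64423.0
  muscle:
    thickness_mm: 6.6
    E_kPa: 2.0
    nu: 0.48
    target_element_count: 98980.0
  bone:
    thickness_mm: 5.0
    E_kPa: 6480.0
    nu: 0.33
    is_linear: yes
    target_element_count: 7890.0
geometry:
  domain_half_width_mm: 60.0
  indenter_radius_mm: 5.0
  roi_radius_mm: 15.0
loads:
  pressures_kPa:
  - 2.0
  - 6.0
  - 8.0
  - 10.0
variants:
  stiffness_reductions:
  - 0.1
  - 0.2
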