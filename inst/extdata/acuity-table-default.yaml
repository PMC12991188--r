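# Representative symptom acuity table, adapted in structure from
# national emergency eye-care triage guidance: emergency-class rules
# encode presentations requiring same-day hospital assessment; the
# remaining bands step down through 24-hour specialist review, 48-hour
# review, routine/one-week review and pharmacist self-care.
# Every vocabulary code is covered by at least one rule (checked at load).
version: "1.0"
vocabulary:
  - red_eye
  - eye_pain_severe
  - eye_pain_mild
  - photophobia
  - nausea_vomiting
  - halos
  - contact_lens_wear
  - discharge_sticky
  - itching
  - gritty
  - dry_irritation
  - vision_loss_sudden
  - vision_loss_gradual
  - vision_blur_mild
  - curtain_shadow
  - flashes_floaters_new
  - double_vision_sudden
  - lid_lump
  - lid_swelling_fever
  - lid_swelling
  - minor_foreign_body
rules:
  # --- emergency presentations (same-day hospital) ---
  - id: E_sudden_vision_loss
    trigger: {all_of: [vision_loss_sudden]}
    level: EMERGENCY_SAME_DAY
    service_hint: ED_EEC
    emergency_class: true
  - id: E_orbital_cellulitis
    trigger: {all_of: [lid_swelling_fever]}
    level: EMERGENCY_SAME_DAY
    service_hint: ED_EEC
    emergency_class: true
  - id: E_angle_closure
    trigger: {all_of: [eye_pain_severe], any_of: [nausea_vomiting, halos]}
    level: EMERGENCY_SAME_DAY
    service_hint: ED_EEC
    emergency_class: true
  # --- urgent (specialist assessment within 24 h) ---
  - id: U_curtain_shadow
    trigger: {all_of: [curtain_shadow]}
    level: URGENT_24H
    service_hint: ED_EEC
  - id: U_flashes_floaters
    trigger: {all_of: [flashes_floaters_new]}
    level: URGENT_24H
    service_hint: MECS_CUES
  - id: U_cl_red_eye
    trigger: {all_of: [contact_lens_wear, red_eye]}
    level: URGENT_24H
    service_hint: MECS_CUES
  - id: U_photophobic_red_eye
    trigger: {all_of: [red_eye, photophobia]}
    level: URGENT_24H
    service_hint: MECS_CUES
  - id: U_sudden_diplopia
    trigger: {all_of: [double_vision_sudden]}
    level: URGENT_24H
    service_hint: ED_EEC
  - id: U_severe_pain
    trigger: {all_of: [eye_pain_severe]}
    level: URGENT_24H
    service_hint: MECS_CUES
  # --- within 48 h ---
  - id: S_red_mild_pain
    trigger: {all_of: [red_eye, eye_pain_mild]}
    level: SOON_48H
  - id: S_mild_blur
    trigger: {all_of: [vision_blur_mild]}
    level: SOON_48H
  - id: S_foreign_body
    trigger: {all_of: [minor_foreign_body]}
    level: SOON_48H
  - id: S_lid_swelling
    trigger: {all_of: [lid_swelling]}
    level: SOON_48H
  # --- within a week / routine ---
  - id: R_gradual_loss
    trigger: {all_of: [vision_loss_gradual]}
    level: ROUTINE_WEEK
  - id: R_lid_lump
    trigger: {all_of: [lid_lump]}
    level: ROUTINE_WEEK
  - id: R_gritty
    trigger: {all_of: [gritty]}
    level: ROUTINE_WEEK
  # --- self-care / pharmacist ---
  - id: C_itching
    trigger: {all_of: [itching]}
    level: SELF_CARE
    service_hint: PHARMACIST
  - id: C_dryness
    trigger: {all_of: [dry_irritation]}
    level: SELF_CARE
    service_hint: PHARMACIST
  - id: C_discharge
    trigger: {all_of: [discharge_sticky]}
    level: SELF_CARE
    service_hint: PHARMACIST
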