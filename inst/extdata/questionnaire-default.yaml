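# Representative default questionnaire for the triage engine.
# The entry question is the complaint filter with the four
# presenting-complaint categories; follow-up questions cover the
# symptom vocabulary of the default acuity table. The engine itself is
# content-agnostic: this document is data, not code.
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
questions:
  - id: q_filter
    text: "Which of these best describes your main problem?"
    select: single
    options:
      - id: red_painful
        label: "Red and/or painful eye or eyes"
      - id: vision
        label: "Painless visual disturbance"
      - id: eyelid
        label: "Eyelid problems"
      - id: injury
        label: "Eye injury"
  - id: q_red_symptoms
    text: "Which of the following do you have? (choose all that apply)"
    select: multiple
    options:
      - id: redness
        label: "Redness of the eye"
        codes: [red_eye]
      - id: pain_severe
        label: "Severe eye pain"
        codes: [eye_pain_severe]
      - id: pain_mild
        label: "Mild ache or soreness"
        codes: [eye_pain_mild]
      - id: light_sensitivity
        label: "Discomfort looking at bright light"
        codes: [photophobia]
      - id: discharge
        label: "Sticky discharge"
        codes: [discharge_sticky]
      - id: itchy
        label: "Itching"
        codes: [itching]
      - id: gritty
        label: "Gritty or foreign-body feeling"
        codes: [gritty]
      - id: dryness
        label: "Dryness or mild irritation"
        codes: [dry_irritation]
      - id: none
        label: "None of these"
  - id: q_red_assoc
    text: "Do you also have any of the following? (choose all that apply)"
    select: multiple
    options:
      - id: nausea_vomiting
        label: "Feeling sick or vomiting with the eye pain"
        codes: [nausea_vomiting]
      - id: halos
        label: "Halos or rainbow rings around lights"
        codes: [halos]
      - id: contact_lens
        label: "I wear contact lenses"
        codes: [contact_lens_wear]
      - id: none
        label: "None of these"
  - id: q_vis_onset
    text: "Which best describes the change in your vision?"
    select: single
    options:
      - id: sudden_loss
        label: "Sudden loss of vision in one or both eyes"
        codes: [vision_loss_sudden]
      - id: curtain
        label: "A shadow or curtain over part of my vision"
        codes: [curtain_shadow]
      - id: flashes_floaters
        label: "New flashes of light or floaters"
        codes: [flashes_floaters_new]
      - id: double_vision
        label: "Sudden double vision"
        codes: [double_vision_sudden]
      - id: gradual_loss
        label: "Gradual blurring over weeks or months"
        codes: [vision_loss_gradual]
      - id: mild_blur
        label: "Mild blurring"
        codes: [vision_blur_mild]
  - id: q_vis_pain
    text: "Is the affected eye painful?"
    select: single
    options:
      - id: painful
        label: "Yes, it is painful"
        codes: [eye_pain_severe]
      - id: painless
        label: "No, it is not painful"
  - id: q_lid_main
    text: "Which best describes the eyelid problem?"
    select: single
    options:
      - id: lump
        label: "A lump or cyst on the lid"
        codes: [lid_lump]
      - id: itchy_crusty
        label: "Itchy, crusty or flaky lids"
        codes: [itching]
      - id: swelling_fever
        label: "Lid swelling with fever or feeling unwell"
        codes: [lid_swelling_fever]
      - id: swelling_no_fever
        label: "Lid swelling without fever"
        codes: [lid_swelling]
  - id: q_injury_type
    text: "What kind of injury was it?"
    select: single
    options:
      - id: chemical
        label: "A chemical or liquid splashed into the eye"
        trauma: chemical
      - id: blunt
        label: "A hard knock or blow to the eye"
        trauma: blunt
      - id: high_velocity
        label: "Something hit the eye at high speed (grinding, hammering, drilling)"
        trauma: high_velocity
      - id: minor
        label: "A minor scratch, or something small in the eye"
        codes: [minor_foreign_body]
  - id: q_injury_assoc
    text: "Since the injury, do you have any of the following? (choose all that apply)"
    select: multiple
    options:
      - id: vision_reduced
        label: "Blurred or reduced vision"
        codes: [vision_blur_mild]
      - id: pain_severe
        label: "Severe pain"
        codes: [eye_pain_severe]
      - id: none
        label: "None of these"
edges:
  - from: q_filter
    when: {any_of: [red_painful]}
    to: q_red_symptoms
  - from: q_filter
    when: {any_of: [vision]}
    to: q_vis_onset
  - from: q_filter
    when: {any_of: [eyelid]}
    to: q_lid_main
  - from: q_filter
    when: {any_of: [injury]}
    to: q_injury_type
  - from: q_filter
    default: true
    to: TERMINAL
  - from: q_red_symptoms
    default: true
    to: q_red_assoc
  - from: q_red_assoc
    default: true
    to: TERMINAL
  - from: q_vis_onset
    when: {any_of: [sudden_loss, curtain]}
    to: q_vis_pain
  - from: q_vis_onset
    default: true
    to: TERMINAL
  - from: q_vis_pain
    default: true
    to: TERMINAL
  - from: q_lid_main
    default: true
    to: TERMINAL
  # potentially severe trauma terminates the questionnaire immediately
  # (fast-path); only minor injuries continue to the follow-up question
  - from: q_injury_type
    when: {any_of: [chemical, blunt, high_velocity]}
    to: TERMINAL
  - from: q_injury_type
    default: true
    to: q_injury_assoc
  - from: q_injury_assoc
    default: true
    to: TERMINAL
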