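# Simulator Sickness Questionnaire: 16 symptoms rated 0-3, canonical
# Kennedy-instrument subscale membership (7 items each, with overlap) and
# weighting factors. Editable data asset.
items:
  - {id: 1,  symptom: general_discomfort,        subscales: [nausea, oculomotor]}
  - {id: 2,  symptom: fatigue,                   subscales: [oculomotor]}
  - {id: 3,  symptom: headache,                  subscales: [oculomotor]}
  - {id: 4,  symptom: eyestrain,                 subscales: [oculomotor]}
  - {id: 5,  symptom: difficulty_focusing,       subscales: [oculomotor, disorientation]}
  - {id: 6,  symptom: increased_salivation,      subscales: [nausea]}
  - {id: 7,  symptom: sweating,                  subscales: [nausea]}
  - {id: 8,  symptom: nausea,                    subscales: [nausea, disorientation]}
  - {id: 9,  symptom: difficulty_concentrating,  subscales: [nausea, oculomotor]}
  - {id: 10, symptom: fullness_of_head,          subscales: [disorientation]}
  - {id: 11, symptom: blurred_vision,            subscales: [oculomotor, disorientation]}
  - {id: 12, symptom: dizziness_eyes_open,       subscales: [disorientation]}
  - {id: 13, symptom: dizziness_eyes_closed,     subscales: [disorientation]}
  - {id: 14, symptom: vertigo,                   subscales: [disorientation]}
  - {id: 15, symptom: stomach_awareness,         subscales: [nausea]}
  - {id: 16, symptom: burping,                   subscales: [nausea]}
weights:
  nausea: 9.54
  oculomotor: 7.58
  disorientation: 13.92
  total: 3.74
rating_range: [0, 3]
actively_ill_threshold: 100
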