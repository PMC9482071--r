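- name: symptom=>symptom
  head_type: symptom
  tail_type: symptom
- name: disease=>symptom
  head_type: disease
  tail_type: symptom
- name: disease=>drug
  head_type: disease
  tail_type: drug
- name: mechanism=>mechanism
  head_type: mechanism
  tail_type: mechanism
- name: symptom=>drug
  head_type: symptom
  tail_type: drug
- name: symptom=>mechanism
  head_type: symptom
  tail_type: mechanism
- name: symptom=>disease
  head_type: symptom
  tail_type: disease
- name: mechanism=>department
  head_type: mechanism
  tail_type: department
- name: symptom=>body parts
  head_type: symptom
  tail_type: body_part
- name: mechanism=>body parts
  head_type: mechanism
  tail_type: body_part
- name: mechanism=>symptom
  head_type: mechanism
  tail_type: symptom
- name: symptom=>department
  head_type: symptom
  tail_type: department
- name: disease=>mechanism
  head_type: disease
  tail_type: mechanism
- name: disease=>body parts
  head_type: disease
  tail_type: body_part
- name: disease=>department
  head_type: disease
  tail_type: department
- name: disease=>disease
  head_type: disease
  tail_type: disease
- name: mechanism =>disease
  head_type: mechanism
  tail_type: disease
- name: drug=>mechanism
  head_type: drug
  tail_type: mechanism
- name: drug=>disease
  head_type: drug
  tail_type: disease
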