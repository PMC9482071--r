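metformin	drug=>mechanism	mechanism:insulin resistance
mechanism:insulin resistance	mechanism =>disease	diabetes mellitus
disease:hypertension	disease=>mechanism	mechanism:liver yang hyperactivity
mechanism:liver yang hyperactivity	mechanism =>disease	disease:dizziness syndrome
symptom:stringy pulse	symptom=>mechanism	mechanism:liver depression
mechanism:liver depression	mechanism=>symptom	symptom:irritability
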