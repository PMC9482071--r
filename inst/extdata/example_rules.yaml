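# Causal composition rules for the synthetic clinical schema: each rule
# whitelists an ordered relation pair whose 2-hop chain is causally
# interpretable, labelled with the implied conclusion relation.
- first: drug=>mechanism
  second: "mechanism =>disease"
  label: drug=>disease
- first: disease=>mechanism
  second: "mechanism =>disease"
  label: disease=>disease
- first: symptom=>mechanism
  second: mechanism=>symptom
  label: symptom=>symptom
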