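# Prioritization — keep drugs whose polar surface area is strictly below
# 60 square angstroms (candidate blood-brain-barrier permeability).
# Equivalent of filter_psa(rows, threshold = 60).
PREFIX vocab: <https://biosemantics.example.org/vocab/>

SELECT ?drug ?drugName ?psa WHERE {
  ?drug vocab:name ?drugName ;
        vocab:psa ?psa .
  FILTER(?psa < 60)
}
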