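# Default translation of ChromHMM chromatin-state names into positive
# (accessible/active) and negative (inaccessible/repressed) evaluation
# labels, for the ENCODE full-stack state vocabulary. States not listed are
# not used for evaluation. Edit or replace to match other state models.
positive:
  - EnhA1
  - EnhA2
  - EnhG1
  - EnhG2
  - TssA
  - TssFlnk
  - TssFlnkD
  - TssFlnkU
  - Tx
negative:
  - Het
  - Quies
  - ReprPC
  - "ZNF/Rpts"
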