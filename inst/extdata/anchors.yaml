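# Cohort anchor-noun lemmas: the focus words around which the cohort
# dependency patterns are built.  The core list covers the standard
# cohort nouns of curated GDA prose; sibling/sib/proband/kindred are
# included because discovery summaries routinely count cohorts in those
# units (e.g. "variants in two siblings").
anchors:
  - family
  - patient
  - child
  - boy
  - girl
  - parent
  - individual
  - people
  - infant
  - woman
  - man
  - sibling
  - sib
  - proband
  - kindred
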