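# gdamine

Rule-based mining of **gene-disease association (GDA) discovery
metadata** from OMIM-style narrative entries.

Catalogues of Mendelian disease genes record *that* a gene causes a
phenotype, but three facts a genetics researcher routinely needs are
buried in free text: **when** the association was first established
(the discovery publication), **how many unrelated individuals or
families** the establishing study reported, and **which model
organisms** supplied supporting evidence. `gdamine` extracts all three
with deterministic, auditable syntactic rules — no statistical model,
no external services — so the same input always yields the same record,
and every extracted field carries provenance (entry, section, sentence).

## Method in brief

1. **Filtration ladder.** Gene-phenotype candidates are enumerated from
   each gene entry's phenotype map and partitioned by the curation
   markers: only mapping key 3 (molecular basis known) survives; labels
   marked `[]` (nondisease), `{}`/"susceptibility", or "modifier" are
   rejected; `?`-labels form a separate *provisional* (typically
   single-patient) stream.
2. **Linguistic analysis.** Each source paragraph is tokenized, tagged,
   lemmatized, and given dependency heads by a deterministic rule-based
   analyzer. Three dependency patterns run over the result:
   - **P1** — a numeric modifier attached directly to a cohort anchor
     noun (*"... in* **6** *unrelated* **patients**"*);
   - **P2** — the numeric on a prepositional mediator reaching the
     anchor (*"***4** *affected members of an unrelated* **family**"*);
   - **exclusion** — an Adverb-Verb-Adposition-Number chain
     (*"was* **previously reported in 4** *patients"*) marking
     phenotype-only describing sentences whose citations must not count
     as discovery evidence.
3. **Proximity citation resolution.** Around each anchor, candidate
   citations are ranked lexicographically by
   *(tier, year, reference number)* with tiers: same sentence →
   preceding sentences → following sentences (never leaving the
   paragraph). Within the first non-empty tier the earliest-year
   reference wins; year ties break to the lower reference number, which
   makes the choice between simultaneous discoveries deterministic.
   References blacklisted by the exclusion pattern are skipped.
4. **Analytics.** Yearly discovery counts per stream, cohort-size
   histograms (with the small-cohort share), model-organism shares in a
   year window, and PMID concordance against a benchmark table.

A synthetic-corpus generator (`generate_corpus()`) plants
machine-readable ground truth behind sentences realized from the same
grammars, with a generation-then-verification loop, so the entire
pipeline is testable without licensed OMIM data.

## Worked example

The MTO1 case — a mitochondrial translation gene whose phenotype
association was established in 2012 in two siblings, with yeast
complementation as supporting evidence:

```r
library(gdamine)
cs <- worked_example_entries()$mto1     # synthetic fixture entries
cand <- extract_gda_candidates(cs$gene) # phenotype-map candidates
rec <- extract_discovery(cs$gene, cs$phenotype, cand[1, ])
print(rec)
#> <gda_record> MTO1 (614667) ~ 614702  [confirmed]
#>   discovery: year 2012, PMID 92000001 (same_sentence)
#>   cohort: n=2 unrelated=FALSE same_study=TRUE
#>   organisms: yeast (2012)
```

The discovery citation was found co-sentential with the gene anchor
(`same_sentence`), the cohort pattern counted two siblings in the same
publication (`same_study=TRUE`), and the animal-model section yielded
the yeast evidence with its study year. (Fixture PMIDs are synthetic.)

Batch extraction and analytics over a generated corpus:

```r
cor <- generate_corpus(fixture_spec(seed = 7, n_entries = 60))
df <- records_table(extract_corpus(cor$catalog))
h <- cohort_size_distribution(df)
print(h)
#>      bin  n      share
#> 1      1 32 0.53333333
#> 2    2-5 17 0.28333333
#> 3   6-10  8 0.13333333
#> 4 11-100  2 0.03333333
#> 5   >100  1 0.01666667
attr(h, "share_lt5")
#> [1] 0.75
```

Three-quarters of these associations rest on fewer than five unrelated
individuals — the small-cohort regime the generator's defaults emulate.

## Command line

```sh
Rscript inst/cli/gdamine.R extract  --entries DIR --out records.jsonl
Rscript inst/cli/gdamine.R fixtures --seed 7 --n 200 --out fixtures/
Rscript inst/cli/gdamine.R trends   --records records.jsonl --out trends/
Rscript inst/cli/gdamine.R benchmark --records records.jsonl \
    --truth benchmark.csv --report report.json
```

Live retrieval (`fetch_entry()`) is cache-first and quota-aware (250
requests/day, persisted per UTC day); an OMIM API key is required and
none of the package's tests or scripts touch the network.

## Scope

Out of scope by design: in-vitro/iPSC/organoid evidence, cross-paragraph
citation search, statistical NER, splitting of legacy multi-gene
phenotype entries, and any redistribution of licensed OMIM content (all
shipped fixtures are synthetic). See the methods vignette
(`vignettes/gda-discovery-mining.Rmd`) for the model, parameter and
design discussion.
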