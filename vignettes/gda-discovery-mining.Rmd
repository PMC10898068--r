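---
title: "Mining gene-disease association discovery metadata: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene-disease association discovery metadata: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdamine)
```

## The problem

Curated catalogues of Mendelian disease genes describe each
gene-disease association (GDA) in expert-written narrative. Three
pieces of discovery metadata live only in that prose: the publication
that first *established* the association (as opposed to earlier work
that merely described patients), the number of unrelated individuals
or families in the establishing study, and the model organisms used as
supporting evidence. Because the text was written by many curators
over decades, its phrasing is heterogeneous; `gdamine` recovers these
fields with explicit syntactic rules whose behaviour can be audited
sentence by sentence.

## The extraction model

### Filtration

A gene entry's phenotype map yields one candidate per row. The ladder
keeps only rows with mapping key 3 (molecular basis known) and a label
free of the nondisease `[]`, susceptibility `{}`/"susceptibility", and
"modifier" markers. Surviving `?`-labels are not discarded: they form
a separate *provisional* stream, because single-patient provisional
associations are tracked as their own trend series downstream and may
later be promoted to confirmed. The three output streams partition the
input exactly — a property the tests assert on planted catalogs.

Two open points were settled as follows. First, no inheritance check
beyond mapping key 3 is applied: the mapping key plus markers already
encode the "established Mendelian association" condition, and a
separate inheritance-string test would re-derive the catalogue's own
classification. Second, rows lacking a phenotype MIM are partitioned
by the same rules but flagged (`has_phenotype_mim = FALSE`); they have
no phenotype entry to mine, so their records degrade to absent fields
rather than being silently dropped.

### Linguistic substrate

No dependency parser is available as an R dependency here, and the
patterns need only a small, well-defined slice of syntax, so the
package ships its own deterministic analyzer: regex tokenization with
citation marks kept atomic (periods inside `{3:Author et al. (2019)}`
never split sentences), lexicon-driven universal POS tagging, a
suffix/irregular-table lemmatizer, and a fixed head-assignment
procedure producing the relations the patterns consume (`nummod`,
`amod`, `det`, `advmod`, `aux`, `prep`, `pobj`, `nsubj`/`obj`,
`conj`). The engine is deliberately simple and fully deterministic:
identical input always produces identical analyses, which is what
makes the extraction auditable. The analyzer is an engine behind a
narrow contract (`analyze_text()` returns a token table), so a richer
parser could be substituted without touching the matchers.

### Patterns

* **P1** fires when a numeric modifier attaches directly to an anchor
  noun. The anchor lemma set ships as YAML
  (`inst/extdata/anchors.yaml`): patient, family, child, boy, girl,
  parent, individual, people, infant, woman, man, plus sibling, sib,
  proband and kindred. The extension beyond the classic cohort nouns
  is a lexicon decision: discovery summaries routinely count cohorts
  in siblings or probands ("found the variant in two siblings"), and
  without those lemmas such cohorts are invisible.
* **P2** covers the alternative attachment geometry: the numeral sits
  on a mediator noun linked to the anchor through a preposition
  ("4 affected members of an unrelated family"), including the
  partitive case ("3 of the probands"). When several numerals compete
  for one anchor, the syntactically closest wins, ties broken
  leftmost.
* The **exclusion pattern** is a dependency-linked
  Adverb-Verb-Adposition-Number chain ("was previously reported in 4
  patients"). It is structural, not lemma-constrained: requiring
  specific verbs ("report", "describe") would buy little precision on
  this prose and would miss curator variation; the adverb requirement
  already separates "previously reported in 4 patients" from "They
  identified variants in 4 patients". Sentences matching it
  contribute no cohort evidence, and their citations are blacklisted
  as phenotype-only studies.
* **Organism detection** accepts species-lexicon tokens
  (`inst/extdata/species.yaml`, 14 canonical keys including the
  livestock additions cattle, chicken, dog) with common- or
  proper-noun POS — "Drosophila" parses as a proper noun.

Cardinal numerals normalize from digits (with thousands separators)
and English words/compounds up to 999; an unparseable numeral leaves
the match with an absent count rather than failing.

### Citation resolution

Candidates are every (mention, reference) pair in the paragraph,
expanded from multi-reference marks, minus the blacklist. They are
ranked lexicographically by *(tier, year, reference number)*, tier
being 0 in the anchor sentence, 1 in preceding sentences, 2 in
following sentences; the search never leaves the paragraph. Proximity
and "earliest study" pull in different directions, and this ordering
resolves their interaction: proximity is the coarse key, year the fine
key within the chosen tier, reference number the deterministic
tie-break for simultaneous discoveries (exactly one of two same-year
studies is ever selected, stably across runs). An independent
brute-force oracle — enumerate all triples, sort — is tested against
the implementation on a thousand randomized paragraphs.

Across source sections, priority is fixed (phenotype entry
`molecularGenetics`, then gene entry `allelicVariants`; for organisms
`animalModel` first): the first section producing any resolution wins,
regardless of its proximity tier. Cohort resolution runs per cohort
match with the same policy, and the earliest resolved cohort study is
reported; it may legitimately differ from the discovery study
(`cohort_same_study` records whether the two reference numbers
coincide).

Degenerate inputs degrade, never fail: a citation-free paragraph, a
fully blacklisted reference set, or a missing section produce a
`tier = "none"` resolution and absent record fields with provenance
noting the miss.

## The synthetic corpus

`generate_corpus()` emulates the statistical structure of real
discovery text: sectioned entries with numbered reference lists,
discovery sentences whose citation sits in the anchor sentence (60%),
a preceding sentence (25%) or a following one (15%); cohort sentences
realized from the P1/P2 grammars with sizes drawn from bins
{1, 2-5, 6-10, 11-100, >100} at proportions (0.40, 0.42, 0.10, 0.07,
0.01) — concentrating below five unrelated individuals, the regime in
which most Mendelian associations are established; a mouse-dominated
organism mix with zebrafish as the main alternative and 71% of
associations carrying organism evidence; 68% of cohort studies being
the discovery study itself; a 15% provisional stream; and optional
exclusion decoys planting an earlier phenotype-describing citation
before the true discovery citation. Each parameter was chosen once,
as stated here, to represent realistic study conditions.

Ground truth is unconditional by construction: after realizing an
entry, the generator replays the full extractor and resamples the
entry if any planted field fails to recover (the manifest records the
resample count, typically 0). This deliberately decouples the truth
table from analyzer quirks — a sentence the engine would mis-attach
never enters a corpus.

What the generator does *not* emulate: curator-era style drift, long
multi-topic paragraphs interleaving several genes, legacy unsplit
phenotype entries covering multiple genes, allelic-variant
subsections, and clinical prose outside the pattern grammars. Passing
the recovery tests therefore demonstrates that the pipeline is correct
*on in-grammar text*, not that recall on real curated text is 100%;
on real text the patterns are intentionally conservative
(precision-first), and sentences outside the grammars yield absent
fields rather than wrong ones.

## Tunable parameters

| Parameter | Default | Where | Why |
|---|---|---|---|
| Anchor lemmas | 15 nouns | `anchors.yaml` | cohort focus words |
| Species lexicon | 14 keys | `species.yaml` | organism evidence |
| Cohort bins | 1, 2-5, 6-10, 11-100, >100 | `cohort_size_distribution(breaks=)` | reporting granularity |
| Organism window | 2011-2021 | `organism_share(window=)` | recent-decade share |
| Daily API budget | 250/day | fetch config | upstream quota |
| Tier mix, bin mix, fractions | see above | `fixture_spec()` | study conditions |

## Problem sizes

The shipped tests and the acceptance script use a 500-candidate
filtration catalog, a 200-entry end-to-end corpus with 20% exclusion
decoys, 1,000 randomized resolver paragraphs, the full 1-999 cardinal
table, and a few hundred randomized trend tables — sizes chosen so the
whole suite exercises every property at comfortable statistical
resolution while remaining quick to run on a laptop.

## Known limitations

* Simultaneous discoveries: only one of several same-year studies is
  reported (lower reference number); the others are ignored.
* The discovery year is the resolved reference's publication year, not
  the catalogue's curation date.
* Cohort counts reflect the sentence as written; "1 of 48 screened
  families" reports the syntactically attached numeral, which may be
  the screening denominator in adversarial phrasings outside the
  tested grammars.
* In-vitro/iPSC/organoid evidence and non-English text are out of
  scope; the organism year is absent when its section has no
  resolvable citation.
* The analyzer's POS/dependency rules target curated biomedical
  summary prose; free-form clinical narrative would need a stronger
  engine behind the same contract.
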