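{
  "_comment": [
    "Annotated example of the OMIM-dialect entry document gdamine reads.",
    "A document holds one entry, optionally wrapped as",
    "omim.entryList[0].entry (the layout of API responses); bare",
    "{\"entry\": ...} or the entry object itself are also accepted.",
    "prefix: '#' phenotype, '*' gene, '+' gene+phenotype, '%' mapped",
    "locus, '^' moved/removed (parsed but marked inactive).",
    "textSectionContent: paragraphs separated by blank lines; inline",
    "citations use brace marks '{N:Author et al. (YYYY)}' resolved by",
    "referenceNumber, or plain 'Author et al. (YYYY)' surface forms",
    "resolved by first author + year.",
    "phenotypeMappingKey: 1-4; 3 = molecular basis known.",
    "This file is a synthetic illustration, not OMIM data."
  ],
  "omim": {
    "entryList": [
      {
        "entry": {
          "prefix": "*",
          "mimNumber": 600100,
          "titles": { "preferredTitle": "EXAMPLE GENE 1; EXG1" },
          "textSectionList": [
            {
              "textSection": {
                "textSectionName": "description",
                "textSectionContent": "The encoded protein participates in ciliary assembly."
              }
            },
            {
              "textSection": {
                "textSectionName": "allelicVariants",
                "textSectionContent": "In affected subjects, {1:Example et al. (2010)} identified an EXG1 variant in 3 unrelated families."
              }
            }
          ],
          "referenceList": [
            {
              "reference": {
                "referenceNumber": 1,
                "firstAuthor": "Example",
                "year": 2010,
                "pubmedID": 90000001
              }
            }
          ],
          "phenotypeMapList": [
            {
              "phenotypeMap": {
                "phenotypeMimNumber": 650100,
                "phenotype": "Example disorder",
                "phenotypeMappingKey": 3,
                "phenotypeInheritance": "Autosomal recessive"
              }
            }
          ]
        }
      }
    ]
  }
}
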