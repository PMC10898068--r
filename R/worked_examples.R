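# Hand-written synthetic fixtures reproducing the structure of four
# instructive real-world gene-disease associations.  These are
# reconstructions for testing, not OMIM text: the narrative is original,
# PMIDs are synthetic, and only the MIM numbers, gene symbols,
# publication years and the structural situation each case illustrates
# are real.
#
#   CUL3 / NEDAUS   -- five citations, the discovery study co-sentential
#                      with the gene anchor (straightforward resolution).
#   MTO1 / COXPD10  -- discovery 2012, cohort of two siblings, yeast
#                      model evidence.
#   KLKB1           -- an early phenotype-describing study precedes the
#                      2003 association-making study and must be skipped.
#   CCDC65 / CILD27 -- two simultaneous 2013 discovery studies; exactly
#                      one is selected, deterministically.

#' Synthetic worked-example entry fixtures
#'
#' Returns four named cases (\code{cul3}, \code{mto1}, \code{klkb1},
#' \code{ccdc65}), each a list with \code{gene} and \code{phenotype}
#' entries plus an \code{expect} list stating the behaviour the case
#' illustrates.  All text is synthetic; see the file header of
#' \code{R/worked_examples.R}.
#'
#' @return named list of cases.
#' @export
worked_example_entries <- function() {
  cases <- list()

  # --- CUL3 -> NEDAUS ---------------------------------------------------
  cul3_refs <- data.frame(
    ref_number = 1:5,
    first_author = c("Boyden", "Ibeawuchi", "Thiffault", "Nakashima",
                     "Dong"),
    year = c(2012L, 2017L, 2019L, 2020L, 2021L),
    pubmed_id = c(91000001L, 91000002L, 91000003L, 91000004L, 91000005L),
    stringsAsFactors = FALSE)
  cul3_phen <- omim_entry(
    619239L, "hash",
    "NEURODEVELOPMENTAL DISORDER WITH OR WITHOUT AUTISM OR SEIZURES; NEDAUS",
    sections = list(molecularGenetics = paste(
      "Variants in this gene were long known in another context {1:Boyden et al. (2012)}.",
      "Further functional work refined the mechanism {2:Ibeawuchi et al. (2017)}.",
      "In affected subjects with neurodevelopmental disease, {3:Thiffault et al. (2019)} identified a de novo mutation in the CUL3 gene.",
      "Additional cases were described {4:Nakashima et al. (2020)}.",
      "A cohort study extended the phenotype {5:Dong et al. (2021)}.")),
    references = cul3_refs)
  cul3_gene <- omim_entry(
    603136L, "asterisk", "CULLIN 3; CUL3",
    phenotype_map = data.frame(
      phenotype_mim = c(619239L, 614496L),
      phenotype_label = c(
        "Neurodevelopmental disorder with or without autism or seizures",
        "Pseudohypoaldosteronism, type IIE"),
      mapping_key = c(3L, 3L),
      inheritance = c("Autosomal dominant", "Autosomal dominant"),
      stringsAsFactors = FALSE))
  cases$cul3 <- list(gene = cul3_gene, phenotype = cul3_phen,
                     expect = list(discovery_year = 2019L,
                                   discovery_pmid = 91000003L,
                                   n_citations = 5L))

  # --- MTO1 -> COXPD10 --------------------------------------------------
  mto1_refs <- data.frame(
    ref_number = 1:2,
    first_author = c("Ghezzi", "Baruffini"),
    year = c(2012L, 2013L),
    pubmed_id = c(92000001L, 92000002L),
    stringsAsFactors = FALSE)
  mto1_phen <- omim_entry(
    614702L, "hash",
    "COMBINED OXIDATIVE PHOSPHORYLATION DEFICIENCY 10; COXPD10",
    sections = list(
      molecularGenetics = paste(
        "In affected subjects with combined oxidative phosphorylation deficiency, {1:Ghezzi et al. (2012)} identified a homozygous mutation in the MTO1 gene.",
        "{1:Ghezzi et al. (2012)} identified the variant in two affected siblings."),
      animalModel = "{1:Ghezzi et al. (2012)} modeled the defect in the yeast and observed impaired respiration."),
    references = mto1_refs)
  mto1_gene <- omim_entry(
    614667L, "asterisk", "MITOCHONDRIAL tRNA TRANSLATION OPTIMIZATION 1; MTO1",
    phenotype_map = data.frame(
      phenotype_mim = 614702L,
      phenotype_label = "Combined oxidative phosphorylation deficiency 10",
      mapping_key = 3L, inheritance = "Autosomal recessive",
      stringsAsFactors = FALSE))
  cases$mto1 <- list(gene = mto1_gene, phenotype = mto1_phen,
                     expect = list(discovery_year = 2012L,
                                   cohort_count = 2L,
                                   organism = "yeast"))

  # --- KLKB1 ------------------------------------------------------------
  klkb1_refs <- data.frame(
    ref_number = 1:2,
    first_author = c("Hathaway", "Lombardi"),
    year = c(1965L, 2003L),
    pubmed_id = c(93000001L, 93000002L),
    stringsAsFactors = FALSE)
  klkb1_phen <- omim_entry(
    612423L, "hash", "FLETCHER FACTOR DEFICIENCY",
    sections = list(molecularGenetics = paste(
      "The trait was previously reported in 11 affected subjects {1:Hathaway et al. (1965)}.",
      "{2:Lombardi et al. (2003)} demonstrated deficiency of plasma prekallikrein at the molecular level.",
      "Mutations in the KLKB1 gene underlie this condition.")),
    references = klkb1_refs)
  klkb1_gene <- omim_entry(
    229000L, "asterisk", "KALLIKREIN B, PLASMA; KLKB1",
    phenotype_map = data.frame(
      phenotype_mim = 612423L,
      phenotype_label = "Fletcher factor deficiency",
      mapping_key = 3L, inheritance = "Autosomal recessive",
      stringsAsFactors = FALSE))
  cases$klkb1 <- list(gene = klkb1_gene, phenotype = klkb1_phen,
                      expect = list(discovery_year = 2003L,
                                    discovery_pmid = 93000002L,
                                    skipped_pmid = 93000001L))

  # --- CCDC65 -> CILD27 -------------------------------------------------
  ccdc65_refs <- data.frame(
    ref_number = 1:2,
    first_author = c("Austin-Tse", "Horani"),
    year = c(2013L, 2013L),
    pubmed_id = c(94000001L, 94000002L),
    stringsAsFactors = FALSE)
  ccdc65_phen <- omim_entry(
    615504L, "hash", "CILIARY DYSKINESIA, PRIMARY, 27; CILD27",
    sections = list(molecularGenetics = paste(
      "In affected subjects with ciliary dyskinesia, {1:Austin-Tse et al. (2013)} and {2:Horani et al. (2013)} independently identified truncating variants in the CCDC65 gene.")),
    references = ccdc65_refs)
  ccdc65_gene <- omim_entry(
    611088L, "asterisk", "COILED-COIL DOMAIN-CONTAINING PROTEIN 65; CCDC65",
    phenotype_map = data.frame(
      phenotype_mim = 615504L,
      phenotype_label = "Ciliary dyskinesia, primary, 27",
      mapping_key = 3L, inheritance = "Autosomal recessive",
      stringsAsFactors = FALSE))
  cases$ccdc65 <- list(gene = ccdc65_gene, phenotype = ccdc65_phen,
                       expect = list(discovery_year = 2013L,
                                     discovery_pmid = 94000001L))

  cases
}
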