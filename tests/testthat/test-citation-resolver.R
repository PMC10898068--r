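mk_refs <- function(years) {
  data.frame(ref_number = seq_along(years),
             first_author = rep("Author", length(years)),
             year = as.integer(years),
             pubmed_id = 80000000L + seq_along(years))
}

paragraph_case <- function(sentences, years) {
  # sentences: character, with "%d" placeholders replaced by citations
  refs <- mk_refs(years)
  doc <- analyze_text(paste(sentences, collapse = " "))
  mentions <- resolve_reference_marks(paste(sentences, collapse = " "),
                                      refs, doc)
  list(doc = doc, mentions = mentions, refs = refs)
}

cite <- function(k, year) sprintf("{%d:Author et al. (%d)}", k, year)

test_that("a co-sentential citation wins over others in the paragraph", {
  cs <- paragraph_case(c(
    sprintf("Early work %s.", cite(1, 1990)),
    sprintf("The GENE1 association was made %s.", cite(2, 2010)),
    sprintf("Later work %s.", cite(3, 2015))), c(1990L, 2010L, 2015L))
  r <- select_citation(cs$doc, 1L, cs$mentions, integer(), cs$refs)
  expect_identical(r$tier, "same_sentence")
  expect_identical(r$ref_number, 2L)
})

test_that("without a co-sentential citation the preceding tier is searched first", {
  cs <- paragraph_case(c(
    sprintf("Early work %s.", cite(1, 1998)),
    "The association was made here.",
    sprintf("Later work %s.", cite(2, 1995))), c(1998L, 1995L))
  r <- select_citation(cs$doc, 1L, cs$mentions, integer(), cs$refs)
  # the following citation is older, but tier dominates year
  expect_identical(r$tier, "preceding")
  expect_identical(r$ref_number, 1L)
})

test_that("citations only in later sentences resolve to the following tier", {
  cs <- paragraph_case(c(
    "The association was made here.",
    "An uncited remark.",
    sprintf("Follow-up %s.", cite(1, 2012))), 2012L)
  r <- select_citation(cs$doc, 0L, cs$mentions, integer(), cs$refs)
  expect_identical(r$tier, "following")
  expect_identical(r$ref_number, 1L)
})

test_that("zero mentions or an all-blacklisted paragraph resolve to none", {
  cs <- paragraph_case("No citations here.", integer())
  expect_identical(select_citation(cs$doc, 0L, cs$mentions, integer(),
                                   cs$refs)$tier, "none")
  cs2 <- paragraph_case(sprintf("Cited once %s.", cite(1, 2000)), 2000L)
  expect_identical(select_citation(cs2$doc, 0L, cs2$mentions, 1L,
                                   cs2$refs)$tier, "none")
})

test_that("within a tier the earliest year wins, ties to the lower ref number", {
  cs <- paragraph_case(sprintf("Both %s and %s made the association.",
                               cite(1, 2013), cite(2, 2013)),
                       c(2013L, 2013L))
  r <- select_citation(cs$doc, 0L, cs$mentions, integer(), cs$refs)
  expect_identical(r$ref_number, 1L)
  cs2 <- paragraph_case(sprintf("Both %s and %s made the association.",
                                cite(1, 2015), cite(2, 2013)),
                        c(2015L, 2013L))
  expect_identical(select_citation(cs2$doc, 0L, cs2$mentions, integer(),
                                   cs2$refs)$ref_number, 2L)
})

test_that("multi-reference mentions expand to one candidate per reference", {
  refs <- mk_refs(c(2005L, 2001L))
  p <- "The association was made {1,2:Author et al. (2005)}."
  m <- resolve_reference_marks(p, refs)
  expect_identical(m$ref_numbers[[1]], c(1L, 2L))
  r <- select_citation(analyze_text(p), 0L, m, integer(), refs)
  expect_identical(r$ref_number, 2L)  # earlier year among the pair
})

test_that("phenotype-only references are exactly the co-sentential ones", {
  p <- paste(
    sprintf("The trait was previously reported in 4 subjects %s.",
            cite(1, 1980)),
    sprintf("Unrelated remark %s.", cite(2, 1999)))
  refs <- mk_refs(c(1980L, 1999L))
  doc <- analyze_text(p)
  mentions <- resolve_reference_marks(p, refs, doc)
  excl <- match_exclusion_pattern(doc)
  expect_identical(phenotype_only_references(doc, mentions, excl), 1L)
  expect_identical(phenotype_only_references(doc, mentions,
                                             excl[0, ]), integer())
})

test_that("no phenotype-describing study exists among the CUL3 citations", {
  cs <- worked_example_entries()$cul3
  p <- cs$phenotype$sections$molecularGenetics[1]
  doc <- analyze_text(p)
  mentions <- resolve_reference_marks(p, cs$phenotype$references, doc)
  expect_identical(nrow(mentions), 5L)
  excl <- match_exclusion_pattern(doc)
  expect_identical(phenotype_only_references(doc, mentions, excl),
                   integer())
})

test_that("section priority dominates proximity tier across sections", {
  none <- structure(list(tier = "none"), class = "resolution_result")
  far <- structure(list(tier = "preceding", ref_number = 9L),
                   class = "resolution_result")
  near <- structure(list(tier = "same_sentence", ref_number = 1L),
                    class = "resolution_result")
  expect_identical(earliest_across_sections(list(none, near))$ref_number, 1L)
  expect_identical(earliest_across_sections(list(far, near))$ref_number, 9L)
  expect_identical(earliest_across_sections(list())$tier, "none")
})

test_that("blacklist monotonicity: growing the blacklist never nears the tier", {
  tier_rank <- c(same_sentence = 0L, preceding = 1L, following = 2L,
                 none = 3L)
  set.seed(402)
  for (i in 1:60) {
    case <- random_resolver_case()
    doc <- analyze_text(case$paragraph)
    mentions <- resolve_reference_marks(case$paragraph, case$references,
                                        doc)
    r0 <- select_citation(doc, case$anchor, mentions, integer(),
                          case$references)
    r1 <- select_citation(doc, case$anchor, mentions, case$blacklist,
                          case$references)
    expect_gte(tier_rank[[r1$tier]], tier_rank[[r0$tier]])
    # tier soundness: a non-blacklisted same-sentence mention forces tier 0
    in_anchor <- any(mentions$sentence_index == case$anchor &
                     !vapply(mentions$ref_numbers, function(r)
                       all(r %in% case$blacklist) || !length(r), TRUE))
    if (in_anchor) expect_identical(r1$tier, "same_sentence")
  }
})

test_that("selection agrees with the brute-force lexicographic oracle", {
  set.seed(77)
  for (i in 1:250) {
    case <- random_resolver_case()
    doc <- analyze_text(case$paragraph)
    mentions <- resolve_reference_marks(case$paragraph, case$references,
                                        doc)
    got <- select_citation(doc, case$anchor, mentions, case$blacklist,
                           case$references)
    want <- resolver_oracle(case)
    if (is.null(want)) {
      expect_identical(got$tier, "none")
    } else {
      expect_identical(got$ref_number, want$ref)
      expect_identical(got$tier, want$tier)
    }
  }
})
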