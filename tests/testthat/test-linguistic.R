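# Gold dependency annotations for the two canonical cohort sentences,
# written by hand: each row fixes the attachment the matcher relies on.
gold_doc <- function(tokens) {
  # tokens: data.frame(text, lemma, pos, dep, head) with 0-based head
  n <- nrow(tokens)
  start <- cumsum(c(0L, nchar(tokens$text[-n]) + 1L))
  tokens$index <- seq_len(n) - 1L
  tokens$sentence_index <- 0L
  tokens$start <- start
  tokens$end <- start + nchar(tokens$text)
  tokens$is_citation <- FALSE
  doc <- list(text = paste(tokens$text, collapse = " "), tokens = tokens,
              sentence_count = 1L)
  class(doc) <- "analyzed_doc"
  doc
}

test_that("the cohort matcher reproduces the hand-annotated gold parses", {
  # "De novo variants were identified in 6 unrelated patients."
  g1 <- gold_doc(data.frame(
    text = c("De", "novo", "variants", "were", "identified", "in", "6",
             "unrelated", "patients", "."),
    lemma = c("de", "novo", "variant", "were", "identify", "in", "6",
              "unrelated", "patient", "."),
    pos = c("ADJ", "ADJ", "NOUN", "AUX", "VERB", "ADP", "NUM", "ADJ",
            "NOUN", "PUNCT"),
    dep = c("amod", "amod", "nsubj", "aux", "ROOT", "prep", "nummod",
            "amod", "pobj", "punct"),
    head = c(2L, 2L, 4L, 4L, 4L, 4L, 8L, 8L, 5L, 4L),
    stringsAsFactors = FALSE))
  m1 <- match_cohort_patterns(g1)
  expect_identical(nrow(m1), 1L)
  expect_identical(m1$anchor_lemma, "patient")
  expect_identical(m1$count, 6L)
  expect_true(m1$unrelated)
  expect_identical(m1$pattern_id, "P1")
  # the live analyzer must agree with the gold parse on these attachments
  a1 <- analyze_text("De novo variants were identified in 6 unrelated patients.")
  expect_identical(match_cohort_patterns(a1)[, names(m1)], m1)

  # "Variants were found in three unrelated families."
  g2 <- gold_doc(data.frame(
    text = c("Variants", "were", "found", "in", "three", "unrelated",
             "families", "."),
    lemma = c("variant", "were", "find", "in", "three", "unrelated",
              "family", "."),
    pos = c("NOUN", "AUX", "VERB", "ADP", "NUM", "ADJ", "NOUN", "PUNCT"),
    dep = c("nsubj", "aux", "ROOT", "prep", "nummod", "amod", "pobj",
            "punct"),
    head = c(2L, 2L, 2L, 2L, 6L, 6L, 3L, 2L),
    stringsAsFactors = FALSE))
  m2 <- match_cohort_patterns(g2)
  expect_identical(m2$anchor_lemma, "family")
  expect_identical(m2$count, 3L)
  expect_true(m2$unrelated)
  a2 <- analyze_text("Variants were found in three unrelated families.")
  expect_identical(match_cohort_patterns(a2)[, names(m2)], m2)
})

test_that("sentences without an anchor lemma yield no cohort match", {
  expect_identical(nrow(match_cohort_patterns(
    analyze_text("The protein localizes to cilia."))), 0L)
})

test_that("the exclusion pattern matches the gold Adverb-Verb-Adposition-Number chain", {
  doc <- analyze_text(
    "This phenotype was previously reported in 4 patients by {2:Smith et al. (1999)}.")
  m <- match_exclusion_pattern(doc)
  expect_identical(nrow(m), 1L)
  expect_identical(m$sentence_index, 0L)
  # no adverb governs the verb here: the gold parse has no match
  expect_identical(nrow(match_exclusion_pattern(
    analyze_text("They identified variants in 4 patients."))), 0L)
  expect_identical(nrow(match_exclusion_pattern(analyze_text(""))), 0L)
})

test_that("analysis basics: empty input, sentence counts, span reconstruction", {
  e <- analyze_text("")
  expect_identical(nrow(e$tokens), 0L)
  expect_identical(e$sentence_count, 0L)
  d <- analyze_text("Mice were studied. Variants were found.")
  expect_identical(d$sentence_count, 2L)
  for (p in c("Knockout mice displayed ataxia.",
              "In 2012, {1:A et al. (2012)} identified ABC1 variants.",
              worked_example_entries()$cul3$phenotype$sections$molecularGenetics)) {
    doc <- analyze_text(p)
    for (i in seq_len(nrow(doc$tokens)))
      expect_identical(substr(p, doc$tokens$start[i] + 1L,
                              doc$tokens$end[i]), doc$tokens$text[i])
    # exactly one root per sentence, heads within the document
    expect_true(all(doc$tokens$head >= 0 &
                    doc$tokens$head < nrow(doc$tokens)))
    roots_per_sentence <- as.integer(tapply(doc$tokens$dep == "ROOT",
                                            doc$tokens$sentence_index, sum))
    expect_identical(roots_per_sentence, rep(1L, doc$sentence_count))
  }
})

test_that("analysis is deterministic", {
  p <- "In affected subjects, {1:A et al. (2001)} identified XYZ2 variants in 6 unrelated patients."
  expect_identical(analyze_text(p), analyze_text(p))
})

test_that("organism detection hits the lexicon as nominal mentions only", {
  for (i in seq_len(nrow(organism_bank()))) {
    row <- organism_bank()[i, ]
    got <- detect_organisms(analyze_text(row$text))
    expect_identical(paste(got$species, collapse = ";"), row$species,
                     info = row$text)
  }
  # duplicate mentions of one species collapse within a sentence
  d <- detect_organisms(analyze_text("Mice and mice and mice were used."))
  expect_identical(nrow(d), 1L)
  # no species word, no mention
  expect_identical(nrow(detect_organisms(
    analyze_text("The patients were studied."))), 0L)
})

test_that("closest numeric modifier wins when several compete", {
  # two numerals, the adjacent one modifies the anchor
  doc <- analyze_text("They studied 12 families and found 3 variants.")
  m <- match_cohort_patterns(doc)
  expect_identical(nrow(m), 1L)
  expect_identical(m$count, 12L)
})

test_that("the full in-grammar cohort bank is recovered (100% recall)", {
  bank <- cohort_bank()
  for (i in seq_len(nrow(bank))) {
    m <- match_cohort_patterns(analyze_text(bank$text[i]))
    expect_identical(nrow(m), 1L, info = bank$text[i])
    expect_identical(m$anchor_lemma, bank$anchor_lemma[i], info = bank$text[i])
    expect_identical(m$count, bank$count[i], info = bank$text[i])
    expect_identical(m$unrelated, bank$unrelated[i], info = bank$text[i])
    expect_identical(m$pattern_id, bank$pattern[i], info = bank$text[i])
  }
})

test_that("the adversarial bank yields no cohort match (100% precision)", {
  for (s in adversarial_bank()) {
    expect_identical(nrow(match_cohort_patterns(analyze_text(s))), 0L,
                     info = s)
  }
})
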