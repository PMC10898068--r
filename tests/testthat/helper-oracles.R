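# Shared independent oracles and sentence-bank builders.

# --- word-number oracle: compositional construction of cardinal words ----
# (independent of normalize_cardinal, which parses)
.ones <- c("one", "two", "three", "four", "five", "six", "seven", "eight",
           "nine")
.teens <- c("ten", "eleven", "twelve", "thirteen", "fourteen", "fifteen",
            "sixteen", "seventeen", "eighteen", "nineteen")
.tens <- c("twenty", "thirty", "forty", "fifty", "sixty", "seventy",
           "eighty", "ninety")

cardinal_word_oracle <- function(n) {
  stopifnot(n >= 1, n <= 999)
  if (n < 10) return(.ones[n])
  if (n < 20) return(.teens[n - 9])
  if (n < 100) {
    t <- .tens[n %/% 10 - 1]
    r <- n %% 10
    return(if (r == 0) t else paste0(t, "-", .ones[r]))
  }
  h <- paste(.ones[n %/% 100], "hundred")
  r <- n %% 100
  if (r == 0) h else paste(h, cardinal_word_oracle(r))
}

# --- grammar banks for the pattern suite ---------------------------------
# In-grammar sentences realized from the P1/P2 shapes with known truth.
cohort_bank <- function() {
  rows <- list()
  add <- function(text, lemma, count, unrelated, pattern) {
    rows[[length(rows) + 1L]] <<- data.frame(
      text = text, anchor_lemma = lemma, count = count,
      unrelated = unrelated, pattern = pattern, stringsAsFactors = FALSE)
  }
  plurals <- c(patients = "patient", families = "family",
               individuals = "individual", children = "child",
               probands = "proband", siblings = "sibling",
               infants = "infant", parents = "parent", women = "woman",
               men = "man", boys = "boy", girls = "girl",
               kindreds = "kindred")
  counts <- c("2", "6", "11", "120", "two", "seven", "twelve",
              "twenty-three")
  i <- 0L
  for (p in names(plurals)) {
    i <- i + 1L
    nw <- counts[(i - 1L) %% length(counts) + 1L]
    nv <- normalize_cardinal(nw)
    add(sprintf("Pathogenic variants were identified in %s unrelated %s.",
                nw, p), plurals[[p]], nv, TRUE, "P1")
    add(sprintf("{1:Rossi et al. (2011)} identified variants in %s affected %s.",
                nw, p), plurals[[p]], nv, FALSE, "P1")
  }
  for (a in c("family", "kindred")) {
    add(sprintf("{1:Rossi et al. (2011)} reported 4 affected members of an unrelated %s.",
                a), a, 4L, TRUE, "P2")
    add(sprintf("They reported three affected members of a consanguineous %s.",
                a), a, 3L, FALSE, "P2")
  }
  add("Variants were found in one affected patient.", "patient", 1L,
      FALSE, "P1")
  do.call(rbind, rows)
}

# Adversarial sentences: an anchor lemma is present but no numeric
# modifier attaches to it.
adversarial_bank <- function() {
  c("The patients were examined by two independent clinicians of the consortium.",
    "Several families were described in the literature.",
    "The 3 variants segregated in the family.",
    "The family history was unremarkable.",
    "Four studies described the patients.",
    "One of the variants segregated in the family.",
    "The parents were healthy.",
    "Affected individuals were recruited.",
    "The proband was diagnosed at 4 years.",
    "Two genes were sequenced in the proband.",
    "The children displayed 2 distinct phenotypes.",
    "The patient carried 3 variants.",
    "A large kindred was ascertained.",
    "Many individuals remained undiagnosed.")
}

exclusion_bank <- function() {
  c("This phenotype was previously reported in 4 patients.",
    "The disorder was originally described in 12 affected subjects.",
    "The condition was initially reported in two families.",
    "Similar cases were formerly described in 7 individuals.",
    "The trait was previously observed in 3 unrelated probands.")
}

# Exclusion adversarial: same vocabulary, no adverb governing the verb.
exclusion_adversarial_bank <- function() {
  c("They identified variants in 4 patients.",
    "The disorder was described in 12 affected subjects.",
    "Variants were reported in two families.")
}

organism_bank <- function() {
  data.frame(
    text = c("Knockout mice displayed ataxia.",
             "Morpholino knockdown in zebrafish embryos reproduced the defect.",
             "They used a yeast model.",
             "Studies in Drosophila confirmed the interaction.",
             "A similar phenotype was observed in the rat.",
             "Mutant worms exhibited locomotion defects.",
             "The gene was disrupted in the dog and in cattle.",
             "Experiments in Xenopus embryos showed mislocalization."),
    species = c("mouse", "zebrafish", "yeast", "drosophila", "rat",
                "worm", "dog;cattle", "xenopus"),
    stringsAsFactors = FALSE)
}

# --- randomized resolver paragraphs with planted truth -------------------
# Builds a paragraph of sentences around one anchor sentence, placing
# citations at random, and returns everything select_citation needs plus
# the planted reference layout.
random_resolver_case <- function() {
  n_sent <- sample(3:6, 1)
  anchor <- sample(seq_len(n_sent), 1) - 1L
  plain <- c("The phenotype is variable.",
             "Expression was reduced in fibroblasts.",
             "The protein localizes to cilia.")
  refs <- list(); sents <- character(n_sent)
  for (s in seq_len(n_sent)) {
    cite_here <- stats::runif(1) < 0.55
    txt <- if (s - 1L == anchor) "Mutations in the GENE1 gene were found"
           else sample(plain, 1)
    txt <- sub("\\.$", "", txt)
    if (cite_here) {
      k <- length(refs) + 1L
      yr <- sample(1980:2020, 1)
      refs[[k]] <- data.frame(ref_number = k, first_author = "Author",
                              year = yr, pubmed_id = 50000000L + k,
                              stringsAsFactors = FALSE)
      txt <- sprintf("%s {%d:Author et al. (%d)}.", txt, k, yr)
    } else txt <- paste0(txt, ".")
    sents[s] <- txt
    attr(sents, "placements") <- rbind(attr(sents, "placements"),
      if (cite_here) data.frame(ref = length(refs), sentence = s - 1L))
  }
  references <- if (length(refs)) do.call(rbind, refs)
                else gdamine:::empty_references()
  blacklist <- if (nrow(references) && stats::runif(1) < 0.4)
    sample(references$ref_number,
           sample(0:nrow(references), 1)) else integer()
  list(paragraph = paste(sents, collapse = " "), anchor = anchor,
       references = references, blacklist = as.integer(blacklist),
       placements = attr(sents, "placements"))
}

# Brute-force lexicographic (tier, year, ref_number) oracle.
resolver_oracle <- function(case) {
  pl <- case$placements
  if (is.null(pl) || nrow(pl) == 0L) return(NULL)
  pl <- pl[!pl$ref %in% case$blacklist, , drop = FALSE]
  if (nrow(pl) == 0L) return(NULL)
  tier <- ifelse(pl$sentence == case$anchor, 0L,
                 ifelse(pl$sentence < case$anchor, 1L, 2L))
  yr <- case$references$year[match(pl$ref, case$references$ref_number)]
  ord <- order(tier, yr, pl$ref)
  list(ref = pl$ref[ord[1]], tier = c("same_sentence", "preceding",
                                      "following")[tier[ord[1]] + 1L])
}

# --- misc ---------------------------------------------------------------
expect_entry_equal <- function(a, b) {
  expect_equal(a$mim_number, b$mim_number)
  expect_equal(a$prefix, b$prefix)
  expect_equal(a$title, b$title)
  expect_equal(names(a$sections), names(b$sections))
  for (nm in names(a$sections))
    expect_equal(a$sections[[nm]], b$sections[[nm]])
  expect_equal(a$references, b$references)
  expect_equal(a$phenotype_map, b$phenotype_map)
}

record_for <- function(case) {
  cand <- extract_gda_candidates(case$gene)
  cand <- cand[cand$phenotype_mim == case$phenotype$mim_number, ,
               drop = FALSE][1, ]
  extract_discovery(case$gene, case$phenotype, cand)
}
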