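# Synthetic OMIM-dialect corpus generator with planted, machine-readable
# ground truth.  Sentences are realized from the same grammars the
# cohort (P1/P2) and exclusion patterns are defined over, citation marks
# are placed according to the proximity-tier mix, and reference lists
# carry consistent years and PMIDs.  A generation-then-verification
# loop replays the extractor on each entry and resamples any entry the
# analyzer mis-attaches, so the truth table is unconditional on parser
# quirks; the resample count is recorded in the manifest.

#' Specification of a synthetic corpus
#'
#' Defaults describe the study conditions the generator emulates:
#' cohort sizes concentrated below five unrelated individuals (the
#' regime in which most associations are established), a mouse-dominated
#' organism mix with zebrafish as the rising alternative, roughly 70%
#' of associations carrying model-organism evidence, a modest
#' provisional (single-patient) stream, and discovery citations mostly
#' co-sentential with the gene anchor.
#'
#' @param seed integer RNG seed.
#' @param n_entries number of gene/phenotype entry pairs.
#' @param cohort_count_distribution named proportions over the bins
#'   \code{1}, \code{2-5}, \code{6-10}, \code{11-100}, \code{>100}.
#' @param organism_mix named proportions over species keys.
#' @param fraction_with_organism share of GDAs with model-organism
#'   evidence.
#' @param fraction_with_exclusion_decoy share of entries planting an
#'   earlier phenotype-describing citation before the true discovery
#'   citation.
#' @param fraction_provisional share of candidates labeled "?".
#' @param citation_tier_mix proportions over
#'   \code{same_sentence}, \code{preceding}, \code{following}.
#' @param fraction_same_study share of GDAs whose cohort publication is
#'   the discovery publication.
#' @param year_range calendar years discovery publications are drawn
#'   from.
#' @return validated list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L,
                         n_entries = 100L,
                         cohort_count_distribution = c(
                           "1" = 0.40, "2-5" = 0.42, "6-10" = 0.10,
                           "11-100" = 0.07, ">100" = 0.01),
                         organism_mix = c(
                           mouse = 0.55, zebrafish = 0.20,
                           drosophila = 0.08, worm = 0.05, rat = 0.04,
                           yeast = 0.04, xenopus = 0.02, dog = 0.01,
                           chicken = 0.01),
                         fraction_with_organism = 0.71,
                         fraction_with_exclusion_decoy = 0,
                         fraction_provisional = 0.15,
                         citation_tier_mix = c(
                           same_sentence = 0.6, preceding = 0.25,
                           following = 0.15),
                         fraction_same_study = 0.68,
                         year_range = c(1986L, 2021L)) {
  spec <- list(seed = as.integer(seed), n_entries = as.integer(n_entries),
               cohort_count_distribution = cohort_count_distribution,
               organism_mix = organism_mix,
               fraction_with_organism = fraction_with_organism,
               fraction_with_exclusion_decoy = fraction_with_exclusion_decoy,
               fraction_provisional = fraction_provisional,
               citation_tier_mix = citation_tier_mix,
               fraction_same_study = fraction_same_study,
               year_range = as.integer(year_range))
  if (spec$n_entries < 1L) stop("n_entries must be >= 1")
  for (nm in c("cohort_count_distribution", "organism_mix",
               "citation_tier_mix")) {
    p <- spec[[nm]]
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stop(sprintf("%s must be proportions summing to 1", nm))
  }
  for (nm in c("fraction_with_organism", "fraction_with_exclusion_decoy",
               "fraction_provisional", "fraction_same_study")) {
    if (spec[[nm]] < 0 || spec[[nm]] > 1)
      stop(sprintf("%s must be in [0, 1]", nm))
  }
  class(spec) <- "fixture_spec"
  spec
}

.bin_bounds <- list("1" = c(1L, 1L), "2-5" = c(2L, 5L), "6-10" = c(6L, 10L),
                    "11-100" = c(11L, 100L), ">100" = c(101L, 400L))

.word_or_digit <- function(n) {
  if (n <= 12L && stats::runif(1) < 0.5) {
    words <- c("one", "two", "three", "four", "five", "six", "seven",
               "eight", "nine", "ten", "eleven", "twelve")
    words[n]
  } else format(n, big.mark = ",")
}

.fake_author <- function() {
  pool <- c("Alder", "Bennett", "Castro", "Dalgaard", "Ekstrom", "Farsi",
            "Gupta", "Hollander", "Ivanova", "Jansen", "Keller", "Lindqvist",
            "Moreau", "Novak", "Okafor", "Petrova", "Quint", "Rossi",
            "Sato", "Tanaka", "Ueda", "Varga", "Weiss", "Yamamoto", "Zhou")
  sample(pool, 1)
}

.cite <- function(ref_number, author, year) {
  sprintf("{%d:%s et al. (%d)}", ref_number, author, year)
}

.species_surface <- function(key) {
  switch(key,
         mouse = "mouse", zebrafish = "zebrafish",
         drosophila = "Drosophila", worm = "worm", yeast = "yeast",
         rat = "rat", xenopus = "Xenopus", rabbit = "rabbit",
         pig = "pig", sheep = "sheep", cattle = "cattle",
         chicken = "chicken", dog = "dog", monkey = "monkey", key)
}

# Realize one entry pair plus its truth row.  Draws fresh randomness on
# each call, so the verification loop can resample.
.realize_entry <- function(i, spec, pmid_base) {
  gene_mim <- 600000L + i
  phen_mim <- 630000L + i
  sym <- sprintf("G%03dA", i)
  provisional <- stats::runif(1) < spec$fraction_provisional
  decoy <- stats::runif(1) < spec$fraction_with_exclusion_decoy
  tier <- sample(names(spec$citation_tier_mix), 1,
                 prob = spec$citation_tier_mix)
  disc_year <- sample(seq(spec$year_range[1], spec$year_range[2]), 1)
  bin <- sample(names(spec$cohort_count_distribution), 1,
                prob = spec$cohort_count_distribution)
  b <- .bin_bounds[[bin]]
  cohort_n <- if (provisional) 1L else sample(seq(b[1], b[2]), 1)
  same_study <- stats::runif(1) < spec$fraction_same_study
  has_org <- stats::runif(1) < spec$fraction_with_organism
  org_keys <- if (has_org) {
    k <- if (stats::runif(1) < 0.15) 2L else 1L
    sample(names(spec$organism_mix), k, prob = spec$organism_mix)
  } else character()

  refs <- list()
  pmid <- pmid_base
  add_ref <- function(author, year) {
    pmid <<- pmid + 1L
    refs[[length(refs) + 1L]] <<- data.frame(
      ref_number = length(refs) + 1L, first_author = author,
      year = year, pubmed_id = pmid, stringsAsFactors = FALSE)
    length(refs)
  }
  decoy_ref <- if (decoy)
    add_ref(.fake_author(), disc_year - sample(2:15, 1)) else NA_integer_
  disc_ref <- add_ref(.fake_author(), disc_year)
  cohort_ref <- if (same_study) disc_ref
                else add_ref(.fake_author(),
                             min(disc_year + sample(0:3, 1), 2022L))
  org_refs <- vapply(org_keys, function(k)
    add_ref(.fake_author(), min(disc_year + sample(0:4, 1), 2022L)), 0L)
  refdf <- do.call(rbind, refs)

  ref_cite <- function(k) .cite(refdf$ref_number[k], refdf$first_author[k],
                                refdf$year[k])

  # discovery paragraph
  decoy_sent <- if (decoy)
    sprintf("The phenotype was previously reported in %d affected subjects %s.",
            sample(2:9, 1), ref_cite(decoy_ref)) else NULL
  disc_sents <- switch(tier,
    same_sentence = sprintf(
      "In affected subjects with this disorder, %s identified a heterozygous mutation in the %s gene.",
      ref_cite(disc_ref), sym),
    preceding = c(
      sprintf("%s described pathogenic variants in a cohort with this disorder.",
              ref_cite(disc_ref)),
      sprintf("Mutations in the %s gene underlie this condition.", sym)),
    following = c(
      sprintf("Mutations in the %s gene cause this disorder.", sym),
      sprintf("%s subsequently confirmed the molecular defect.",
              ref_cite(disc_ref))))
  para_disc <- paste(c(decoy_sent, disc_sents), collapse = " ")

  # cohort paragraph
  unrelated <- if (cohort_n == 1L) FALSE else stats::runif(1) < 0.6
  pattern <- if (cohort_n == 1L || stats::runif(1) < 0.6) "P1" else "P2"
  nw <- .word_or_digit(cohort_n)
  para_cohort <- if (pattern == "P1") {
    anchor <- if (cohort_n == 1L)
      sample(c("patient", "child", "proband", "infant", "boy", "girl"), 1)
    else
      sample(c("patients", "individuals", "families", "children",
               "probands", "infants", "siblings"), 1)
    sprintf("%s identified disease-causing variants in %s %s%s.",
            ref_cite(cohort_ref), nw,
            if (unrelated) "unrelated " else "affected ", anchor)
  } else {
    anchor <- sample(c("family", "kindred"), 1)
    sprintf("%s reported %s affected members of %s %s.",
            ref_cite(cohort_ref), nw,
            if (unrelated) "an unrelated" else "a consanguineous", anchor)
  }

  # animal-model paragraph
  para_org <- if (length(org_keys)) {
    paste(vapply(seq_along(org_keys), function(j)
      sprintf("%s modeled the disorder in the %s and observed comparable defects.",
              ref_cite(org_refs[j]), .species_surface(org_keys[j])), ""),
      collapse = " ")
  } else NULL

  label <- sprintf("%sDevelopmental disorder %d",
                   if (provisional) "?" else "", i)
  pmap <- data.frame(phenotype_mim = phen_mim, phenotype_label = label,
                     mapping_key = 3L,
                     inheritance = "Autosomal recessive",
                     stringsAsFactors = FALSE)
  # occasional extra rejected row to exercise the filtration ladder
  if (stats::runif(1) < 0.25) {
    pmap <- rbind(pmap, data.frame(
      phenotype_mim = phen_mim + 20000L,
      phenotype_label = sprintf("{Immune disease %d, susceptibility to}", i),
      mapping_key = 3L, inheritance = "", stringsAsFactors = FALSE))
  }
  gene <- omim_entry(gene_mim, "asterisk",
                     sprintf("SYNTHETIC GENE %d; %s", i, sym),
                     sections = list(
                       description = "The encoded protein participates in core cellular pathways."),
                     phenotype_map = pmap)
  sections <- list(molecularGenetics = c(para_disc, para_cohort))
  if (!is.null(para_org)) sections$animalModel <- para_org
  phen <- omim_entry(phen_mim, "hash", toupper(label), sections = sections,
                     references = refdf)

  truth <- data.frame(
    gene_mim = gene_mim, phenotype_mim = phen_mim, gene_symbol = sym,
    stream = if (provisional) "provisional" else "confirmed",
    tier = tier, decoy = decoy,
    decoy_pmid = if (decoy) refdf$pubmed_id[decoy_ref] else NA_integer_,
    discovery_year = disc_year,
    discovery_pmid = refdf$pubmed_id[disc_ref],
    cohort_count = cohort_n, cohort_unrelated = unrelated,
    cohort_pattern = pattern, cohort_same_study = same_study,
    organisms = paste(sort(org_keys), collapse = ";"),
    organism_years = paste(refdf$year[org_refs[order(org_keys)]],
                           collapse = ";"),
    stringsAsFactors = FALSE)
  list(gene = gene, phen = phen, truth = truth, n_pmids = pmid - pmid_base)
}

# TRUE when replaying the extractor reproduces the planted truth.
.verify_entry <- function(gene, phen, truth) {
  cand <- extract_gda_candidates(gene)
  part <- partition_candidates(cand)
  keep <- rbind(part$confirmed, part$provisional)
  keep <- keep[keep$phenotype_mim == truth$phenotype_mim, , drop = FALSE]
  if (nrow(keep) != 1L) return(FALSE)
  rec <- extract_discovery(gene, phen, keep[1, ])
  org <- paste(sort(rec$organisms$species), collapse = ";")
  identical(rec$stream, truth$stream) &&
    isTRUE(rec$discovery_pmid == truth$discovery_pmid) &&
    isTRUE(rec$discovery_year == truth$discovery_year) &&
    isTRUE(rec$cohort_count == truth$cohort_count) &&
    isTRUE(rec$cohort_unrelated == truth$cohort_unrelated) &&
    isTRUE(rec$cohort_same_study == truth$cohort_same_study) &&
    identical(org, truth$organisms) &&
    (!truth$decoy || !isTRUE(rec$discovery_pmid == truth$decoy_pmid))
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Deterministic for a fixed spec (seed included): returns the entry
#' catalog, the truth table with the expected value of every extracted
#' field, and a manifest recording the seed and the number of sentence
#' resamples the verification loop needed.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list with \code{catalog} (genes + phenotypes, ready for
#'   \code{\link{extract_corpus}}), \code{truth} (data.frame) and
#'   \code{manifest}.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  genes <- list()
  phenotypes <- list()
  truths <- list()
  resamples <- 0L
  pmid_base <- 20000000L
  for (i in seq_len(spec$n_entries)) {
    for (attempt in 1:10) {
      r <- .realize_entry(i, spec, pmid_base)
      if (.verify_entry(r$gene, r$phen, r$truth)) break
      resamples <- resamples + 1L
      if (attempt == 10L)
        stop(sprintf("entry %d could not be realized in-grammar", i))
    }
    pmid_base <- pmid_base + r$n_pmids
    genes[[length(genes) + 1L]] <- r$gene
    phenotypes[[as.character(r$phen$mim_number)]] <- r$phen
    truths[[length(truths) + 1L]] <- r$truth
  }
  list(catalog = list(genes = genes, phenotypes = phenotypes),
       truth = do.call(rbind, truths),
       manifest = list(seed = spec$seed, n_entries = spec$n_entries,
                       engine = "gdamine deterministic analyzer v1",
                       resamples = resamples))
}

#' Generate a candidate catalog with planted partition assignment
#'
#' Builds \code{n} gene-phenotype candidates whose mapping keys and
#' label markers realize a stream assignment drawn first (the planted
#' truth), for testing the filtration ladder against exact expected
#' stream sizes.
#'
#' @param n number of candidates.
#' @param seed RNG seed.
#' @param probs named proportions for confirmed/provisional/rejected.
#' @return list with \code{candidates} (data.frame in
#'   \code{\link{extract_gda_candidates}} layout) and \code{truth}
#'   (planted stream per candidate).
#' @export
generate_candidate_catalog <- function(n, seed = 1L,
                                       probs = c(confirmed = 0.50,
                                                 provisional = 0.12,
                                                 rejected = 0.38)) {
  set.seed(seed)
  stream <- sample(names(probs), n, replace = TRUE, prob = probs)
  rows <- lapply(seq_len(n), function(i) {
    key <- 3L
    label <- sprintf("Planted disorder %d", i)
    if (stream[i] == "provisional") {
      label <- paste0("?", label)
    } else if (stream[i] == "rejected") {
      mode <- sample(c("key", "nondisease", "susceptibility", "modifier"), 1)
      if (mode == "key") key <- sample(c(1L, 2L, 4L), 1)
      else if (mode == "nondisease") label <- sprintf("[%s]", label)
      else if (mode == "susceptibility")
        label <- sprintf("{%s, susceptibility to}", label)
      else label <- paste(label, "modifier of severity")
    }
    fl <- classify_phenotype_markers(label)
    data.frame(gene_mim = 600000L + i, phenotype_mim = 650000L + i,
               phenotype_label = label, mapping_key = key,
               inheritance = "", nondisease = fl[["nondisease"]],
               susceptibility = fl[["susceptibility"]],
               provisional = fl[["provisional"]],
               modifier = fl[["modifier"]], has_phenotype_mim = TRUE,
               stringsAsFactors = FALSE)
  })
  list(candidates = do.call(rbind, rows), truth = stream)
}
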