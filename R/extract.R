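# Per-GDA extraction: choose prioritized source sections, run the
# patterns, resolve citations, and assemble the discovery record.
#
# Section priority follows the curation conventions: the discovery
# publication and cohort evidence are sought in the phenotype entry's
# molecularGenetics section first, then the gene entry's
# allelicVariants; model organisms in the phenotype entry's animalModel
# section first, falling back to molecularGenetics and allelicVariants.

.section_plan <- function(gene_entry, phenotype_entry) {
  plan <- list()
  if (!is.null(phenotype_entry)) {
    plan[[length(plan) + 1L]] <- list(entry = phenotype_entry,
                                      section = "molecularGenetics")
  }
  plan[[length(plan) + 1L]] <- list(entry = gene_entry,
                                    section = "allelicVariants")
  plan
}

# Analyze every paragraph of a section once; returns a list of
# per-paragraph bundles (doc, mentions, exclusions, blacklist).
.analyze_section <- function(entry, section) {
  paras <- entry$sections[[section]]
  if (is.null(paras) || !length(paras)) return(list())
  lapply(seq_along(paras), function(i) {
    doc <- analyze_text(paras[i])
    mentions <- resolve_reference_marks(paras[i], entry$references, doc)
    exclusions <- match_exclusion_pattern(doc)
    blacklist <- phenotype_only_references(doc, mentions, exclusions)
    list(paragraph = i, doc = doc, mentions = mentions,
         exclusions = exclusions, blacklist = blacklist,
         entry_mim = entry$mim_number, section = section,
         references = entry$references)
  })
}

# First sentence containing the gene symbol as a token, or NA.
.anchor_sentence <- function(doc, symbol) {
  tk <- doc$tokens
  hit <- which(toupper(tk$text) == toupper(symbol) & !tk$is_citation)
  if (length(hit)) tk$sentence_index[hit[1]] else NA_integer_
}

#' Extract the discovery record for one gene-disease association
#'
#' Runs the full per-GDA workflow: finds the discovery publication with
#' the gene symbol as anchor in the prioritized sections (excluding
#' phenotype-only studies), extracts cohort size and unrelatedness from
#' the cohort patterns with their own citation resolution, and detects
#' model organisms with the nearest-then-earliest reference attached.
#' Missing sections degrade to absent fields.
#'
#' @param gene_entry the gene \code{omim_entry}.
#' @param phenotype_entry the phenotype \code{omim_entry}, or NULL when
#'   unavailable.
#' @param gda one row of \code{\link{extract_gda_candidates}} output
#'   (confirmed or provisional).
#' @param gene_symbol anchor symbol; defaults to the symbol decoded
#'   from the gene entry title.
#' @return object of class \code{gda_record}.
#' @export
extract_discovery <- function(gene_entry, phenotype_entry, gda,
                              gene_symbol = omim_gene_symbol(gene_entry)) {
  plan <- .section_plan(gene_entry, phenotype_entry)
  bundles <- unlist(lapply(plan, function(p)
    .analyze_section(p$entry, p$section)), recursive = FALSE)
  provenance <- list()

  # --- discovery publication -------------------------------------------
  disc_results <- list()
  disc_prov <- list()
  for (b in bundles) {
    sent <- .anchor_sentence(b$doc, gene_symbol)
    if (is.na(sent)) next
    res <- select_citation(b$doc, sent, b$mentions, b$blacklist,
                           b$references)
    disc_results[[length(disc_results) + 1L]] <- res
    disc_prov[[length(disc_prov) + 1L]] <-
      list(entry = b$entry_mim, section = b$section,
           paragraph = b$paragraph, sentence = sent)
  }
  disc <- earliest_across_sections(disc_results)
  if (!identical(disc$tier, "none")) {
    k <- which(vapply(disc_results, function(r) !identical(r$tier, "none"),
                      TRUE))[1]
    provenance$discovery <- disc_prov[[k]]
    disc_src <- disc_prov[[k]]
  } else {
    provenance$discovery <- list(missing = "no resolvable citation near anchor")
    disc_src <- NULL
  }

  # --- cohort -----------------------------------------------------------
  cohort <- list(count = NA_integer_, unrelated = NA, pattern = NA_character_,
                 ref_number = NA_integer_, year = NA_integer_,
                 pubmed_id = NA_integer_, entry = NA_integer_)
  for (sec in unique(vapply(bundles, `[[`, "", "section"))) {
    sec_bundles <- Filter(function(b) b$section == sec, bundles)
    found <- list()
    for (b in sec_bundles) {
      mm <- match_cohort_patterns(b$doc)
      if (nrow(mm) == 0L) next
      bad_sent <- unique(b$exclusions$sentence_index)
      mm <- mm[!mm$sentence_index %in% bad_sent, , drop = FALSE]
      for (j in seq_len(nrow(mm))) {
        res <- select_citation(b$doc, mm$sentence_index[j], b$mentions,
                               b$blacklist, b$references)
        found[[length(found) + 1L]] <- list(match = mm[j, ], res = res, b = b)
      }
    }
    if (!length(found)) next
    resolved <- Filter(function(f) !identical(f$res$tier, "none"), found)
    pick <- if (length(resolved)) {
      keys <- vapply(resolved, function(f)
        f$res$year * 10000 + f$res$ref_number, 0)
      resolved[[which.min(keys)]]
    } else {
      found[[which.min(vapply(found, function(f)
        f$match$sentence_index, 0L))]]
    }
    cohort$count <- pick$match$count
    cohort$unrelated <- pick$match$unrelated
    cohort$pattern <- pick$match$pattern_id
    cohort$ref_number <- pick$res$ref_number
    cohort$year <- pick$res$year
    cohort$pubmed_id <- pick$res$pubmed_id
    cohort$entry <- pick$b$entry_mim
    provenance$cohort <- list(entry = pick$b$entry_mim,
                              section = pick$b$section,
                              paragraph = pick$b$paragraph,
                              sentence = pick$match$sentence_index)
    break
  }

  # --- organisms --------------------------------------------------------
  org_plan <- list()
  if (!is.null(phenotype_entry)) {
    org_plan <- c(org_plan,
                  .analyze_section(phenotype_entry, "animalModel"),
                  Filter(function(b)
                    b$entry_mim == phenotype_entry$mim_number &&
                    b$section == "molecularGenetics", bundles))
  }
  org_plan <- c(org_plan, Filter(function(b)
    b$section == "allelicVariants", bundles))
  organisms <- data.frame(species = character(), year = integer(),
                          stringsAsFactors = FALSE)
  org_prov <- list()
  for (b in org_plan) {
    om <- detect_organisms(b$doc)
    if (nrow(om) == 0L) next
    for (j in seq_len(nrow(om))) {
      sp <- om$species[j]
      if (sp %in% organisms$species) next
      res <- select_citation(b$doc, om$sentence_index[j], b$mentions,
                             b$blacklist, b$references)
      organisms <- rbind(organisms, data.frame(
        species = sp,
        year = if (identical(res$tier, "none")) NA_integer_ else res$year,
        stringsAsFactors = FALSE))
      org_prov[[sp]] <- list(entry = b$entry_mim, section = b$section,
                             paragraph = b$paragraph,
                             sentence = om$sentence_index[j])
    }
  }
  provenance$organisms <- org_prov

  same_study <- if (is.na(cohort$ref_number) ||
                    identical(disc$tier, "none") || is.null(disc_src)) NA
                else (cohort$entry == disc_src$entry &&
                      cohort$ref_number == disc$ref_number)

  structure(list(
    gene_mim = gda$gene_mim,
    phenotype_mim = gda$phenotype_mim,
    gene_symbol = gene_symbol,
    stream = if (isTRUE(gda$provisional)) "provisional" else "confirmed",
    discovery_year = if (identical(disc$tier, "none")) NA_integer_
                     else disc$year,
    discovery_pmid = if (identical(disc$tier, "none")) NA_integer_
                     else disc$pubmed_id,
    discovery_tier = disc$tier,
    cohort_count = cohort$count,
    cohort_unrelated = cohort$unrelated,
    cohort_year = cohort$year,
    cohort_pmid = cohort$pubmed_id,
    cohort_same_study = same_study,
    organisms = organisms,
    provenance = provenance
  ), class = "gda_record")
}

#' @export
print.gda_record <- function(x, ...) {
  cat(sprintf("<gda_record> %s (%d) ~ %s  [%s]\n", x$gene_symbol,
              x$gene_mim, ifelse(is.na(x$phenotype_mim), "?",
                                 x$phenotype_mim), x$stream))
  cat(sprintf("  discovery: year %s, PMID %s (%s)\n",
              ifelse(is.na(x$discovery_year), "?", x$discovery_year),
              ifelse(is.na(x$discovery_pmid), "?", x$discovery_pmid),
              x$discovery_tier))
  cat(sprintf("  cohort: n=%s unrelated=%s same_study=%s\n",
              ifelse(is.na(x$cohort_count), "?", x$cohort_count),
              ifelse(is.na(x$cohort_unrelated), "?", x$cohort_unrelated),
              ifelse(is.na(x$cohort_same_study), "?", x$cohort_same_study)))
  cat(sprintf("  organisms: %s\n",
              if (nrow(x$organisms)) paste0(x$organisms$species, " (",
                                            ifelse(is.na(x$organisms$year),
                                                   "?", x$organisms$year),
                                            ")", collapse = ", ")
              else "none"))
  invisible(x)
}

#' Batch extraction over a catalog of entries
#'
#' Filters each gene entry's candidates, keeps the confirmed and
#' provisional streams, extracts one discovery record per GDA against
#' its own phenotype entry, and returns the records sorted by
#' (gene_mim, phenotype_mim).  Per-entry failures are collected as
#' warnings; the batch never aborts.
#'
#' @param catalog list with \code{genes} (list of gene
#'   \code{omim_entry}) and \code{phenotypes} (list of phenotype
#'   entries, named by MIM number).
#' @param progress logical; emit a message per gene entry.
#' @return list of \code{gda_record}, class \code{gda_record_list}.
#' @export
extract_corpus <- function(catalog, progress = FALSE) {
  records <- list()
  failures <- character()
  phen_names <- names(catalog$phenotypes)
  for (g in catalog$genes) {
    res <- tryCatch({
      cand <- extract_gda_candidates(g)
      part <- partition_candidates(cand)
      keep <- rbind(part$confirmed, part$provisional)
      out <- list()
      for (i in seq_len(nrow(keep))) {
        gda <- keep[i, ]
        pe <- if (!is.na(gda$phenotype_mim) &&
                  as.character(gda$phenotype_mim) %in% phen_names)
          catalog$phenotypes[[as.character(gda$phenotype_mim)]] else NULL
        out[[length(out) + 1L]] <- extract_discovery(g, pe, gda)
      }
      out
    }, error = function(e) {
      failures <<- c(failures,
                     sprintf("entry %d: %s", g$mim_number,
                             conditionMessage(e)))
      list()
    })
    records <- c(records, res)
    if (progress) message(sprintf("processed gene %d (%d records)",
                                  g$mim_number, length(res)))
  }
  if (length(failures))
    warning(sprintf("%d entr%s failed: %s", length(failures),
                    if (length(failures) == 1L) "y" else "ies",
                    paste(failures, collapse = "; ")))
  ord <- order(vapply(records, `[[`, 0L, "gene_mim"),
               vapply(records, function(r)
                 ifelse(is.na(r$phenotype_mim), Inf,
                        r$phenotype_mim), 0))
  records <- records[ord]
  class(records) <- "gda_record_list"
  records
}

#' Flatten discovery records to a table
#'
#' @param records a \code{gda_record_list} (or plain list of
#'   \code{gda_record}).
#' @return data.frame, one row per record; organisms are collapsed to a
#'   "species:year" semicolon string in \code{organisms}, with the raw
#'   per-record data.frames in the \code{organism_table} list column.
#' @export
records_table <- function(records) {
  if (inherits(records, "gda_record")) records <- list(records)
  df <- data.frame(
    gene_mim = vapply(records, `[[`, 0L, "gene_mim"),
    phenotype_mim = vapply(records, function(r)
      as.integer(r$phenotype_mim), 0L),
    gene_symbol = vapply(records, `[[`, "", "gene_symbol"),
    stream = vapply(records, `[[`, "", "stream"),
    discovery_year = vapply(records, function(r)
      as.integer(r$discovery_year), 0L),
    discovery_pmid = vapply(records, function(r)
      as.integer(r$discovery_pmid), 0L),
    discovery_tier = vapply(records, `[[`, "", "discovery_tier"),
    cohort_count = vapply(records, function(r)
      as.integer(r$cohort_count), 0L),
    cohort_unrelated = vapply(records, function(r)
      as.logical(r$cohort_unrelated), NA),
    cohort_same_study = vapply(records, function(r)
      as.logical(r$cohort_same_study), NA),
    organisms = vapply(records, function(r)
      if (nrow(r$organisms)) paste0(r$organisms$species, ":",
                                    ifelse(is.na(r$organisms$year), "NA",
                                           r$organisms$year),
                                    collapse = ";") else "", ""),
    stringsAsFactors = FALSE)
  df$organism_table <- lapply(records, `[[`, "organisms")
  df
}

#' Write discovery records as JSONL
#'
#' @param records a \code{gda_record_list}.
#' @param path output file.
#' @return invisibly, the number of lines written.
#' @export
write_records_jsonl <- function(records, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in records) {
    x <- unclass(r)
    x$provenance <- NULL
    x$organisms <- if (nrow(r$organisms))
      lapply(seq_len(nrow(r$organisms)), function(i)
        list(species = r$organisms$species[i],
             year = r$organisms$year[i]))
      else list()
    writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                             null = "null", na = "null")),
               con)
  }
  invisible(length(records))
}
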