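# Proximity-based selection of the publication evidencing a match.
#
# Candidate citations are ranked lexicographically by
# (tier, year, ref_number): tier 0 = anchor sentence, 1 = preceding
# sentences, 2 = following sentences (search never leaves the
# paragraph).  Within the first non-empty tier the earliest-year
# reference wins; year ties break to the lower reference number (this
# is what makes the choice between simultaneous discoveries
# deterministic).  Blacklisted (phenotype-only) references are skipped.

.none_result <- function(blacklist = integer()) {
  structure(list(tier = "none", ref_number = NA_integer_,
                 year = NA_integer_, pubmed_id = NA_integer_,
                 mention = NA_integer_,
                 excluded_refs = as.integer(blacklist),
                 candidates = data.frame()),
            class = "resolution_result")
}

#' References cited only by phenotype-describing sentences
#'
#' Returns the reference numbers of every citation mention that is
#' co-sentential with an exclusion-pattern match in the same document.
#'
#' @param doc the analyzed paragraph.
#' @param mentions \code{\link{resolve_reference_marks}} output for the
#'   same paragraph.
#' @param exclusions \code{\link{match_exclusion_pattern}} output for
#'   the same paragraph.
#' @return integer vector of reference numbers (possibly empty).
#' @export
phenotype_only_references <- function(doc, mentions, exclusions) {
  if (nrow(mentions) == 0L || nrow(exclusions) == 0L) return(integer())
  bad_sent <- unique(exclusions$sentence_index)
  hit <- mentions$sentence_index %in% bad_sent
  sort(unique(unlist(mentions$ref_numbers[hit])))
}

#' Select the citation evidencing an anchor
#'
#' Searches proximity tiers in order -- the anchor sentence, then
#' preceding sentences, then following sentences to the paragraph end
#' -- skipping blacklisted references, and within the first non-empty
#' tier selects the earliest-year reference (ties to the lower
#' reference number).  Mentions carrying several reference numbers
#' expand to one candidate per reference.
#'
#' @param doc the analyzed paragraph (used for the sentence count
#'   precondition).
#' @param anchor_sentence 0-based sentence index of the anchor token.
#' @param mentions mention data.frame for the paragraph.
#' @param blacklist integer reference numbers to skip.
#' @param references the entry's reference data.frame.
#' @return object of class \code{resolution_result}: list with
#'   \code{tier} ("same_sentence", "preceding", "following" or
#'   "none"), \code{ref_number}, \code{year}, \code{pubmed_id},
#'   \code{mention} (row index into \code{mentions}),
#'   \code{excluded_refs} and the ranked \code{candidates} table.
#' @export
select_citation <- function(doc, anchor_sentence, mentions,
                            blacklist = integer(), references) {
  stopifnot(anchor_sentence >= 0L, anchor_sentence < doc$sentence_count)
  if (nrow(mentions) == 0L) return(.none_result(blacklist))
  cand <- do.call(rbind, lapply(seq_len(nrow(mentions)), function(i) {
    refs <- mentions$ref_numbers[[i]]
    if (length(refs) == 0L) return(NULL)
    data.frame(mention = i, ref_number = as.integer(refs),
               sentence_index = mentions$sentence_index[i])
  }))
  if (is.null(cand) || nrow(cand) == 0L) return(.none_result(blacklist))
  cand <- cand[!cand$ref_number %in% blacklist, , drop = FALSE]
  if (nrow(cand) == 0L) return(.none_result(blacklist))
  cand$tier <- ifelse(cand$sentence_index == anchor_sentence, 0L,
                      ifelse(cand$sentence_index < anchor_sentence, 1L, 2L))
  m <- match(cand$ref_number, references$ref_number)
  cand$year <- references$year[m]
  cand$pubmed_id <- references$pubmed_id[m]
  cand <- cand[order(cand$tier, cand$year, cand$ref_number), , drop = FALSE]
  top <- cand[1, ]
  structure(list(
    tier = c("same_sentence", "preceding", "following")[top$tier + 1L],
    ref_number = top$ref_number,
    year = top$year,
    pubmed_id = top$pubmed_id,
    mention = top$mention,
    excluded_refs = as.integer(blacklist),
    candidates = cand), class = "resolution_result")
}

#' Combine resolutions across prioritized source sections
#'
#' Given resolution results ordered by section priority (phenotype
#' molecularGenetics before gene allelicVariants), the first result
#' that found a citation wins regardless of its proximity tier;
#' all-none propagates none.
#'
#' @param results list of \code{resolution_result}s in priority order.
#' @return a \code{resolution_result}.
#' @export
earliest_across_sections <- function(results) {
  for (r in results) {
    if (!identical(r$tier, "none")) return(r)
  }
  .none_result()
}

#' @export
print.resolution_result <- function(x, ...) {
  if (identical(x$tier, "none")) {
    cat("<resolution_result> none\n")
  } else {
    cat(sprintf("<resolution_result> tier=%s ref=%d year=%d pmid=%s\n",
                x$tier, x$ref_number, x$year,
                ifelse(is.na(x$pubmed_id), "NA", x$pubmed_id)))
  }
  invisible(x)
}
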