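# Inline citation detection and resolution against the numbered
# reference list.  Two dialects are supported: brace-numbered marks
# ("{5:Thiffault et al. (2019)}"), resolved by reference number, and
# plain author-year surface citations ("Smith et al. (2001)"), resolved
# by first-author + year lookup.  Unresolvable mentions are returned
# flagged, never fatal.

#' Resolve inline citation marks in a paragraph
#'
#' Finds every inline citation in document order and resolves it
#' against the entry's reference list.  Character spans are 0-based
#' half-open offsets into the paragraph; sentence indices come from the
#' linguistic analyzer.
#'
#' @param paragraph character scalar.
#' @param references reference data.frame of the owning entry
#'   (columns \code{ref_number}, \code{first_author}, \code{year},
#'   \code{pubmed_id}).
#' @param doc optional pre-computed \code{\link{analyze_text}} result
#'   for the same paragraph (re-analyzed when omitted).
#' @return data.frame with one row per mention: \code{surface},
#'   \code{start}, \code{end}, \code{sentence_index},
#'   \code{ref_numbers} (list column of integers), \code{resolved}.
#' @export
resolve_reference_marks <- function(paragraph, references, doc = NULL) {
  if (is.null(doc)) doc <- analyze_text(paragraph)
  tk <- doc$tokens
  cites <- tk[tk$is_citation, , drop = FALSE]
  out <- data.frame(surface = character(), start = integer(),
                    end = integer(), sentence_index = integer(),
                    resolved = logical(), stringsAsFactors = FALSE)
  out$ref_numbers <- list()
  if (nrow(cites) == 0L) return(out)
  rows <- lapply(seq_len(nrow(cites)), function(i) {
    surf <- cites$text[i]
    refn <- integer()
    resolved <- FALSE
    if (startsWith(surf, "{")) {
      nums <- regmatches(surf, regexpr("^\\{[0-9, ]+:", surf))
      nums <- gsub("[{}:]", "", nums)
      cand <- as.integer(strsplit(nums, "[ ]?,[ ]?")[[1]])
      refn <- cand[cand %in% references$ref_number]
      resolved <- length(refn) == length(cand) && length(refn) > 0L
    } else {
      author <- regmatches(surf, regexpr("^[A-Z][A-Za-z'-]+", surf))
      yr <- as.integer(gsub("[()]", "",
                            regmatches(surf, regexpr("\\([0-9]{4}\\)", surf))))
      hit <- which(!is.na(references$year) & references$year == yr &
                   tolower(vapply(strsplit(references$first_author, "[ ,]"),
                                  `[`, "", 1L)) == tolower(author))
      refn <- references$ref_number[hit]
      resolved <- length(refn) > 0L
    }
    list(surface = surf, start = cites$start[i], end = cites$end[i],
         sentence_index = cites$sentence_index[i],
         ref_numbers = as.integer(refn), resolved = resolved)
  })
  out <- data.frame(
    surface = vapply(rows, `[[`, "", "surface"),
    start = vapply(rows, `[[`, 0L, "start"),
    end = vapply(rows, `[[`, 0L, "end"),
    sentence_index = vapply(rows, `[[`, 0L, "sentence_index"),
    resolved = vapply(rows, `[[`, FALSE, "resolved"),
    stringsAsFactors = FALSE)
  out$ref_numbers <- lapply(rows, `[[`, "ref_numbers")
  out
}
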