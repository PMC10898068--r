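# The filtration ladder over gene-phenotype candidates: enumerate
# phenotype-map rows, classify their label markers, and partition into
# confirmed / provisional / rejected streams.  Only mapping key 3 (the
# molecular basis of the phenotype is known) survives; labels marked
# nondisease "[]", susceptibility "{}"/"susceptibility", or "modifier"
# are rejected; surviving "?" labels are kept as a separate provisional
# stream rather than discarded, because they are tracked as
# single-patient provisional associations downstream.

#' Classify phenotype label markers
#'
#' Decodes the curation markers carried by a phenotype label:
#' \code{[]} nondisease, \code{\{\}} or the word "susceptibility"
#' (case-insensitive, whole word) susceptibility, leading \code{?}
#' provisional, and the word "modifier".
#'
#' @param label non-empty phenotype label as printed.
#' @return named logical vector with elements \code{nondisease},
#'   \code{susceptibility}, \code{provisional}, \code{modifier}.
#' @examples
#' classify_phenotype_markers("?Neurodevelopmental disorder")
#' classify_phenotype_markers("{Asthma, susceptibility to}")
#' @export
classify_phenotype_markers <- function(label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  s <- trimws(label)
  core <- sub("^[\\[{]", "", s)
  c(nondisease = startsWith(s, "["),
    susceptibility = startsWith(s, "{") ||
      grepl("\\bsusceptibility\\b", s, ignore.case = TRUE),
    provisional = startsWith(core, "?"),
    modifier = grepl("\\bmodifier\\b", s, ignore.case = TRUE))
}

#' Enumerate gene-phenotype candidates from a gene entry
#'
#' One candidate per phenotype-map row, with marker flags computed from
#' the label.  Rows lacking a phenotype MIM are kept but flagged
#' (\code{has_phenotype_mim = FALSE}); there is no phenotype entry to
#' mine for them.
#'
#' @param gene_entry an \code{omim_entry} with a phenotype map
#'   (possibly empty).
#' @return data.frame with columns \code{gene_mim},
#'   \code{phenotype_mim}, \code{phenotype_label}, \code{mapping_key},
#'   \code{inheritance}, the four marker flags and
#'   \code{has_phenotype_mim}.
#' @export
extract_gda_candidates <- function(gene_entry) {
  pm <- gene_entry$phenotype_map
  out <- data.frame(gene_mim = integer(), phenotype_mim = integer(),
                    phenotype_label = character(), mapping_key = integer(),
                    inheritance = character(), nondisease = logical(),
                    susceptibility = logical(), provisional = logical(),
                    modifier = logical(), has_phenotype_mim = logical(),
                    stringsAsFactors = FALSE)
  if (nrow(pm) == 0L) return(out)
  flags <- t(vapply(pm$phenotype_label, classify_phenotype_markers,
                    logical(4)))
  data.frame(gene_mim = gene_entry$mim_number,
             phenotype_mim = pm$phenotype_mim,
             phenotype_label = pm$phenotype_label,
             mapping_key = pm$mapping_key,
             inheritance = pm$inheritance,
             nondisease = flags[, "nondisease"],
             susceptibility = flags[, "susceptibility"],
             provisional = flags[, "provisional"],
             modifier = flags[, "modifier"],
             has_phenotype_mim = !is.na(pm$phenotype_mim),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition candidates into confirmed / provisional / rejected
#'
#' Rejected: mapping key not 3, or any of the nondisease,
#' susceptibility or modifier markers.  Provisional: survivors whose
#' label is marked "?".  Confirmed: the remaining survivors.  The
#' three streams partition the input exactly.
#'
#' @param candidates data.frame from
#'   \code{\link{extract_gda_candidates}} (possibly rbind-ed over many
#'   genes).
#' @return list with data.frames \code{confirmed}, \code{provisional},
#'   \code{rejected}, each carrying a \code{stream} column.
#' @export
partition_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    empty <- cbind(candidates, data.frame(stream = character()))
    return(list(confirmed = empty, provisional = empty, rejected = empty))
  }
  rejected <- candidates$mapping_key != 3L | candidates$nondisease |
    candidates$susceptibility | candidates$modifier
  provisional <- !rejected & candidates$provisional
  confirmed <- !rejected & !provisional
  tag <- function(df, lab) {
    if (nrow(df)) df$stream <- lab else df$stream <- character(0)
    rownames(df) <- NULL
    df
  }
  list(confirmed = tag(candidates[confirmed, , drop = FALSE], "confirmed"),
       provisional = tag(candidates[provisional, , drop = FALSE],
                         "provisional"),
       rejected = tag(candidates[rejected, , drop = FALSE], "rejected"))
}

#' Write a partition as stream-tagged JSONL
#'
#' One JSON object per candidate with its stream tag, plus a counts
#' summary as a sibling JSON file when \code{summary_path} is given.
#'
#' @param partition result of \code{\link{partition_candidates}}.
#' @param path output JSONL file.
#' @param summary_path optional JSON file for the per-stream counts.
#' @return invisibly, the counts summary list.
#' @export
write_partition_jsonl <- function(partition, path, summary_path = NULL) {
  all <- rbind(partition$confirmed, partition$provisional,
               partition$rejected)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(all))) {
    writeLines(as.character(jsonlite::toJSON(as.list(all[i, ]),
                                             auto_unbox = TRUE)), con)
  }
  counts <- list(confirmed = nrow(partition$confirmed),
                 provisional = nrow(partition$provisional),
                 rejected = nrow(partition$rejected),
                 total = nrow(all))
  if (!is.null(summary_path))
    jsonlite::write_json(counts, summary_path, auto_unbox = TRUE)
  invisible(counts)
}
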