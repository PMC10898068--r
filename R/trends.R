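# Trend aggregation and benchmark concordance over discovery records.

.as_records_df <- function(records) {
  if (is.data.frame(records)) records else records_table(records)
}

#' Yearly counts of discovered associations
#'
#' Counts discovery records per calendar year for the requested stream;
#' records without a resolved discovery year are tallied separately in
#' the \code{n_year_unknown} attribute.
#'
#' @param records a \code{gda_record_list} or \code{\link{records_table}}
#'   data.frame.
#' @param stream "confirmed", "provisional" or "both".
#' @return data.frame with \code{year}, \code{n}, sorted by year;
#'   attribute \code{n_year_unknown}.
#' @export
yearly_counts <- function(records, stream = c("both", "confirmed",
                                              "provisional")) {
  stream <- match.arg(stream)
  df <- .as_records_df(records)
  if (stream != "both") df <- df[df$stream == stream, , drop = FALSE]
  known <- df[!is.na(df$discovery_year), , drop = FALSE]
  if (nrow(known) == 0L) {
    out <- data.frame(year = integer(), n = integer())
  } else {
    tab <- table(known$discovery_year)
    out <- data.frame(year = as.integer(names(tab)),
                      n = as.integer(tab))
    out <- out[order(out$year), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "n_year_unknown") <- nrow(df) - nrow(known)
  out
}

#' Cohort-size distribution
#'
#' Histogram of the number of unrelated individuals/families in the
#' initial studies, over configurable bins; also reports the share of
#' records with fewer than five individuals as the
#' \code{share_lt5} attribute (the small-cohort share).
#'
#' @param records records list or table.
#' @param breaks strictly increasing integer upper bin edges; the
#'   default \code{c(1, 5, 10, 100)} yields bins 1, 2-5, 6-10, 11-100,
#'   >100.
#' @return data.frame with \code{bin}, \code{n}, \code{share};
#'   attributes \code{n_missing} and \code{share_lt5}.
#' @export
cohort_size_distribution <- function(records, breaks = c(1L, 5L, 10L, 100L)) {
  stopifnot(all(diff(breaks) > 0))
  df <- .as_records_df(records)
  cnt <- df$cohort_count
  n_missing <- sum(is.na(cnt))
  cnt <- cnt[!is.na(cnt)]
  lab <- character(length(breaks) + 1L)
  lab[1] <- as.character(breaks[1])
  if (length(breaks) > 1L)
    for (i in 2:length(breaks))
      lab[i] <- if (breaks[i - 1] + 1L == breaks[i])
        as.character(breaks[i])
      else sprintf("%d-%d", breaks[i - 1] + 1L, breaks[i])
  lab[length(lab)] <- sprintf(">%d", breaks[length(breaks)])
  if (length(cnt) == 0L) {
    out <- data.frame(bin = character(), n = integer(), share = numeric())
    attr(out, "n_missing") <- n_missing
    attr(out, "share_lt5") <- NA_real_
    return(out)
  }
  idx <- findInterval(cnt, breaks + 1L) + 1L   # bin index per count
  tab <- tabulate(idx, nbins = length(lab))
  keep <- tab > 0L
  out <- data.frame(bin = lab[keep], n = tab[keep],
                    share = tab[keep] / length(cnt),
                    stringsAsFactors = FALSE)
  attr(out, "n_missing") <- n_missing
  attr(out, "share_lt5") <- mean(cnt < 5L)
  out
}

#' Model-organism shares within a year window
#'
#' Per-species counts and shares among records carrying at least one
#' organism, restricted to organism study years inside the window.
#'
#' @param records records list or table.
#' @param window inclusive year range, default the 2011-2021 decade.
#' @return data.frame with \code{species}, \code{n}, \code{share},
#'   sorted by decreasing share.
#' @export
organism_share <- function(records, window = c(2011L, 2021L)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  df <- .as_records_df(records)
  sp <- character()
  for (tb in df$organism_table) {
    if (is.null(tb) || nrow(tb) == 0L) next
    ok <- !is.na(tb$year) & tb$year >= window[1] & tb$year <= window[2]
    sp <- c(sp, tb$species[ok])
  }
  if (!length(sp))
    return(data.frame(species = character(), n = integer(),
                      share = numeric()))
  tab <- sort(table(sp), decreasing = TRUE)
  data.frame(species = names(tab), n = as.integer(tab),
             share = as.integer(tab) / length(sp),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare extracted discovery publications with a benchmark table
#'
#' Per-GDA PMID equality against a benchmark keyed by
#' (gene_mim, phenotype_mim).  Records absent from the benchmark are
#' reported separately and excluded from the comparison; duplicate
#' benchmark keys are an error.  The conflict list is returned for
#' manual review.
#'
#' @param records records list or table.
#' @param benchmark data.frame with columns \code{gene_mim},
#'   \code{phenotype_mim}, \code{pmid}.
#' @return list of class \code{match_report}: \code{n_compared},
#'   \code{n_matched}, \code{n_conflicting},
#'   \code{n_absent_in_benchmark}, \code{match_share},
#'   \code{conflicts} (data.frame).
#' @export
compare_to_benchmark <- function(records, benchmark) {
  stopifnot(all(c("gene_mim", "phenotype_mim", "pmid") %in%
                names(benchmark)))
  bkey <- paste(benchmark$gene_mim, benchmark$phenotype_mim)
  if (anyDuplicated(bkey))
    stop("duplicate (gene_mim, phenotype_mim) keys in benchmark")
  df <- .as_records_df(records)
  rkey <- paste(df$gene_mim, df$phenotype_mim)
  m <- match(rkey, bkey)
  absent <- is.na(m)
  cmp <- df[!absent, , drop = FALSE]
  bm <- benchmark$pmid[m[!absent]]
  matched <- !is.na(cmp$discovery_pmid) & cmp$discovery_pmid == bm
  conflicts <- data.frame(gene_mim = cmp$gene_mim[!matched],
                          phenotype_mim = cmp$phenotype_mim[!matched],
                          extracted_pmid = cmp$discovery_pmid[!matched],
                          benchmark_pmid = bm[!matched])
  structure(list(
    n_compared = nrow(cmp),
    n_matched = sum(matched),
    n_conflicting = sum(!matched),
    n_absent_in_benchmark = sum(absent),
    match_share = if (nrow(cmp)) sum(matched) / nrow(cmp) else NA_real_,
    conflicts = conflicts), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> compared %d: matched %d (%.2f%%), conflicting %d; absent from benchmark %d\n",
    x$n_compared, x$n_matched, 100 * x$match_share, x$n_conflicting,
    x$n_absent_in_benchmark))
  invisible(x)
}

#' Read a benchmark CSV
#'
#' Expects columns \code{gene_mim}, \code{phenotype_mim}, \code{pmid}.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_benchmark_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_mim", "phenotype_mim", "pmid") %in% names(df)))
  df
}
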