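# Domain model for one OMIM-dialect entry and its JSON (de)serialization.
#
# The dialect mirrors the OMIM API response layout: an entry object with
# mimNumber, prefix, titles$preferredTitle, textSectionList,
# referenceList and phenotypeMapList, optionally wrapped as
# {"omim": {"entryList": [{"entry": ...}]}}.  An annotated fixture
# documenting the dialect ships under inst/extdata/.

.prefix_map <- c("#" = "hash", "*" = "asterisk", "+" = "plus",
                 "%" = "percent", "^" = "caret")

.schema_error <- function(field) {
  stop(structure(
    class = c("gdamine_schema_error", "error", "condition"),
    list(message = sprintf("malformed entry document: missing or invalid field '%s'",
                           field), call = NULL)))
}

empty_references <- function() {
  data.frame(ref_number = integer(), first_author = character(),
             year = integer(), pubmed_id = integer(),
             stringsAsFactors = FALSE)
}

empty_phenotype_map <- function() {
  data.frame(phenotype_mim = integer(), phenotype_label = character(),
             mapping_key = integer(), inheritance = character(),
             stringsAsFactors = FALSE)
}

#' Construct an OMIM entry object
#'
#' Low-level constructor with validity checks; most users will obtain
#' entries via \code{\link{parse_omim_entry}} or
#' \code{\link{fetch_entry}}.
#'
#' @param mim_number integer, 6-digit MIM identifier.
#' @param prefix one of "hash", "asterisk", "plus", "percent", "caret",
#'   "none".  Caret (moved/removed) entries are parsed but marked
#'   inactive.
#' @param title entry title; gene entries conventionally carry the gene
#'   symbol after a semicolon ("CULLIN 3; CUL3").
#' @param sections named list: canonical section key ->
#'   character vector of paragraphs.
#' @param references data.frame with columns \code{ref_number},
#'   \code{first_author}, \code{year}, \code{pubmed_id}.
#' @param phenotype_map data.frame with columns \code{phenotype_mim},
#'   \code{phenotype_label}, \code{mapping_key}, \code{inheritance}
#'   (gene entries; may be empty).
#' @return object of class \code{omim_entry}.
#' @export
omim_entry <- function(mim_number, prefix = "none", title = "",
                       sections = list(), references = empty_references(),
                       phenotype_map = empty_phenotype_map()) {
  e <- structure(list(
    mim_number = as.integer(mim_number),
    prefix = prefix,
    active = !identical(prefix, "caret"),
    title = as.character(title),
    sections = sections,
    references = references,
    phenotype_map = phenotype_map
  ), class = "omim_entry")
  validate_omim_entry(e)
  e
}

#' Validate an OMIM entry object
#'
#' Checks the structural invariants: 6-digit MIM number, known prefix,
#' unique reference numbers, plausible years, mapping keys in 1..4.
#'
#' @param entry an \code{omim_entry}.
#' @return the entry, invisibly; signals a
#'   \code{gdamine_schema_error} otherwise.
#' @export
validate_omim_entry <- function(entry) {
  if (is.na(entry$mim_number) || entry$mim_number < 100000L ||
      entry$mim_number > 999999L)
    .schema_error("mimNumber")
  if (!entry$prefix %in% c(unname(.prefix_map), "none"))
    .schema_error("prefix")
  if (!is.list(entry$sections) ||
      (length(entry$sections) && is.null(names(entry$sections))))
    .schema_error("textSectionList")
  r <- entry$references
  if (!all(c("ref_number", "first_author", "year", "pubmed_id") %in% names(r)))
    .schema_error("referenceList")
  if (anyDuplicated(r$ref_number))
    .schema_error("referenceNumber (duplicated)")
  if (nrow(r) && any(r$ref_number < 1L, na.rm = TRUE))
    .schema_error("referenceNumber")
  yr_now <- as.integer(format(Sys.Date(), "%Y"))
  if (nrow(r) && any(!is.na(r$year) & (r$year < 1850L | r$year > yr_now)))
    .schema_error("reference year")
  pm <- entry$phenotype_map
  if (!all(c("phenotype_mim", "phenotype_label", "mapping_key",
             "inheritance") %in% names(pm)))
    .schema_error("phenotypeMapList")
  if (nrow(pm) && any(!pm$mapping_key %in% 1:4))
    .schema_error("phenotypeMappingKey")
  invisible(entry)
}

#' @export
print.omim_entry <- function(x, ...) {
  sym <- names(.prefix_map)[match(x$prefix, .prefix_map)]
  if (is.na(sym)) sym <- ""
  cat(sprintf("<omim_entry> %s%d  %s\n", sym, x$mim_number, x$title))
  cat(sprintf("  sections: %s\n",
              if (length(x$sections)) paste(names(x$sections), collapse = ", ")
              else "(none)"))
  cat(sprintf("  references: %d, phenotype map rows: %d\n",
              nrow(x$references), nrow(x$phenotype_map)))
  invisible(x)
}

.int_or_na <- function(x) {
  if (is.null(x) || length(x) == 0L || (is.character(x) && !nzchar(x)))
    return(NA_integer_)
  suppressWarnings(as.integer(x))
}

#' Parse an OMIM-dialect JSON document into an entry
#'
#' Accepts a file path, a JSON string, or an already-deserialized list
#' in the OMIM API layout (optionally wrapped in
#' \code{omim$entryList[[1]]$entry}).  All text sections, references and
#' phenotype-map rows are captured; unknown section names are preserved
#' verbatim; the prefix is decoded from the entry's symbol.
#'
#' @param raw path, JSON string, or list.
#' @return an \code{omim_entry}.
#' @export
parse_omim_entry <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) {
    if (file.exists(raw)) raw <- paste(readLines(raw, warn = FALSE),
                                       collapse = "\n")
    raw <- jsonlite::fromJSON(raw, simplifyVector = FALSE)
  }
  if (!is.list(raw)) .schema_error("document")
  ent <- raw
  if (!is.null(ent$omim)) ent <- ent$omim
  if (!is.null(ent$entryList)) {
    if (length(ent$entryList) < 1L) .schema_error("entryList")
    ent <- ent$entryList[[1]]
  }
  if (!is.null(ent$entry)) ent <- ent$entry
  if (is.null(ent$mimNumber)) .schema_error("mimNumber")
  mim <- .int_or_na(ent$mimNumber)
  pfx_sym <- if (is.null(ent$prefix)) "" else as.character(ent$prefix)
  prefix <- if (pfx_sym %in% names(.prefix_map)) unname(.prefix_map[pfx_sym])
            else "none"
  title <- if (!is.null(ent$titles$preferredTitle)) ent$titles$preferredTitle
           else if (!is.null(ent$title)) ent$title else ""
  sections <- list()
  for (ts in ent$textSectionList %||% list()) {
    sec <- ts$textSection %||% ts
    nm <- sec$textSectionName
    if (is.null(nm) || !nzchar(nm)) .schema_error("textSectionName")
    content <- sec$textSectionContent %||% ""
    paras <- strsplit(content, "\n\n", fixed = TRUE)[[1]]
    paras <- paras[nzchar(trimws(paras))]
    sections[[nm]] <- c(sections[[nm]], paras)
  }
  refs <- list()
  for (rr in ent$referenceList %||% list()) {
    ref <- rr$reference %||% rr
    if (is.null(ref$referenceNumber)) .schema_error("referenceNumber")
    refs[[length(refs) + 1L]] <- data.frame(
      ref_number = .int_or_na(ref$referenceNumber),
      first_author = as.character(ref$firstAuthor %||%
                                  strsplit(ref$authors %||% "", ",")[[1]][1] %||% ""),
      year = .int_or_na(ref$year %||% ref$pubDate),
      pubmed_id = .int_or_na(ref$pubmedID),
      stringsAsFactors = FALSE)
  }
  references <- if (length(refs)) do.call(rbind, refs) else empty_references()
  pmaps <- list()
  for (pm in ent$phenotypeMapList %||% list()) {
    row <- pm$phenotypeMap %||% pm
    pmaps[[length(pmaps) + 1L]] <- data.frame(
      phenotype_mim = .int_or_na(row$phenotypeMimNumber),
      phenotype_label = as.character(row$phenotype %||% ""),
      mapping_key = .int_or_na(row$phenotypeMappingKey),
      inheritance = as.character(row$phenotypeInheritance %||% ""),
      stringsAsFactors = FALSE)
  }
  phenotype_map <- if (length(pmaps)) do.call(rbind, pmaps)
                   else empty_phenotype_map()
  omim_entry(mim, prefix, title, sections, references, phenotype_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an entry back to the OMIM JSON dialect
#'
#' Inverse of \code{\link{parse_omim_entry}}:
#' \code{parse_omim_entry(omim_entry_to_json(e))} reproduces \code{e}.
#'
#' @param entry an \code{omim_entry}.
#' @param path optional file to write to.
#' @return JSON string (invisibly when \code{path} is given).
#' @export
omim_entry_to_json <- function(entry, path = NULL) {
  sym <- names(.prefix_map)[match(entry$prefix, .prefix_map)]
  ent <- list(
    prefix = if (is.na(sym)) "" else sym,
    mimNumber = entry$mim_number,
    titles = list(preferredTitle = entry$title),
    textSectionList = lapply(names(entry$sections), function(nm) {
      list(textSection = list(
        textSectionName = nm,
        textSectionContent = paste(entry$sections[[nm]], collapse = "\n\n")))
    }),
    referenceList = lapply(seq_len(nrow(entry$references)), function(i) {
      r <- entry$references[i, ]
      list(reference = list(
        referenceNumber = r$ref_number,
        firstAuthor = r$first_author,
        year = r$year,
        pubmedID = if (is.na(r$pubmed_id)) NULL else r$pubmed_id))
    }),
    phenotypeMapList = lapply(seq_len(nrow(entry$phenotype_map)), function(i) {
      p <- entry$phenotype_map[i, ]
      list(phenotypeMap = list(
        phenotypeMimNumber = if (is.na(p$phenotype_mim)) NULL
                             else p$phenotype_mim,
        phenotype = p$phenotype_label,
        phenotypeMappingKey = p$mapping_key,
        phenotypeInheritance = p$inheritance))
    })
  )
  js <- jsonlite::toJSON(list(omim = list(entryList = list(list(entry = ent)))),
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

# Gene symbol from a title of the form "LONG NAME; SYMBOL".
omim_gene_symbol <- function(entry) {
  parts <- strsplit(entry$title, ";[ ]*")[[1]]
  if (length(parts) >= 2L) trimws(parts[length(parts)])
  else strsplit(trimws(entry$title), "[ ]+")[[1]][1]
}
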