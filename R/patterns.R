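# Dependency patterns over analyzed documents.
#
# P1: an anchor noun (patient/family/...) carrying a direct numeric
#     modifier ("... in 6 unrelated patients").
# P2: the alternative attachment geometry: the numeric modifier sits on
#     a mediator reached from the anchor through a prepositional link
#     ("4 affected members of an unrelated family", "3 of the
#     probands").
# Exclusion: a dependency-linked Adverb-Verb-Adposition-Number sequence
#     ("... was previously reported in 4 patients ...") marking
#     phenotype-only describing sentences whose citations must not be
#     taken as discovery evidence.
# Organism: nominal tokens from the species lexicon.

.children <- function(tokens, i0) {
  which(tokens$head == i0 & tokens$index != i0) # 1-based rows of children
}

#' Match cohort patterns in an analyzed document
#'
#' Fires P1 when a numeric modifier attaches directly to an anchor
#' noun, and P2 when the numeric reaches the anchor through a
#' prepositional mediator within the same sentence.  When several
#' numeric modifiers compete, the syntactically closest wins, ties
#' broken leftmost.  \code{unrelated} is set when an adjectival
#' modifier lemmatizing to "unrelated" attaches to the anchor (or, for
#' P2, to the mediator).
#'
#' @param doc an \code{\link{analyze_text}} result.
#' @param anchors anchor lemma set (default
#'   \code{\link{default_anchor_lemmas}}).
#' @return data.frame with one row per match: \code{anchor_index},
#'   \code{anchor_lemma}, \code{count} (NA when the numeral cannot be
#'   normalized), \code{unrelated}, \code{pattern_id} ("P1"/"P2"),
#'   \code{sentence_index}.
#' @export
match_cohort_patterns <- function(doc, anchors = default_anchor_lemmas()) {
  tk <- doc$tokens
  out <- data.frame(anchor_index = integer(), anchor_lemma = character(),
                    count = integer(), unrelated = logical(),
                    pattern_id = character(), sentence_index = integer(),
                    stringsAsFactors = FALSE)
  if (nrow(tk) == 0L) return(out)
  anchor_rows <- which(tk$pos %in% c("NOUN", "PROPN") & tk$lemma %in% anchors)
  rows <- list()
  for (a in anchor_rows) {
    a0 <- tk$index[a]
    sent <- tk$sentence_index[a]
    kids <- .children(tk, a0)
    kids <- kids[tk$sentence_index[kids] == sent]
    num_kids <- kids[tk$pos[kids] == "NUM" & tk$dep[kids] == "nummod"]
    pattern <- NA_character_
    num_row <- NA_integer_
    mediator <- NA_integer_
    if (length(num_kids)) {
      # syntactically closest numeric modifier; ties broken leftmost
      d <- abs(num_kids - a)
      num_row <- num_kids[order(d, num_kids)][1]
      pattern <- "P1"
    } else {
      # follow the anchor's head chain through one prepositional link
      h <- tk$head[a] + 1L                      # row of anchor's head
      if (h != a && tk$pos[h] == "ADP" && tk$sentence_index[h] == sent) {
        g <- tk$head[h] + 1L                    # head of the adposition
        if (g != h && tk$sentence_index[g] == sent) {
          if (tk$pos[g] %in% c("NOUN", "PROPN")) {
            gk <- .children(tk, tk$index[g])
            gnum <- gk[tk$pos[gk] == "NUM" & tk$dep[gk] == "nummod" &
                       tk$sentence_index[gk] == sent]
            if (length(gnum)) {
              d <- abs(gnum - g)
              num_row <- gnum[order(d, gnum)][1]
              mediator <- g
              pattern <- "P2"
            }
          } else if (tk$pos[g] == "NUM") {      # partitive: "3 of the probands"
            num_row <- g
            pattern <- "P2"
          }
        }
      }
    }
    if (is.na(pattern)) next
    cnt <- tryCatch(normalize_cardinal(tk$text[num_row]),
                    gdamine_numeral_error = function(e) NA_integer_)
    unrel_on <- function(i) {
      kk <- .children(tk, tk$index[i])
      any(tk$dep[kk] == "amod" & tk$lemma[kk] == "unrelated")
    }
    unrel <- unrel_on(a) || (!is.na(mediator) && unrel_on(mediator))
    rows[[length(rows) + 1L]] <- data.frame(
      anchor_index = a0, anchor_lemma = tk$lemma[a],
      count = as.integer(cnt), unrelated = unrel, pattern_id = pattern,
      sentence_index = sent, stringsAsFactors = FALSE)
  }
  if (length(rows)) do.call(rbind, rows) else out
}

#' Match the exclusion pattern
#'
#' Detects dependency-linked Adverb-Verb-Adposition-Number sequences
#' ("previously reported in 4 ..."), which mark sentences that merely
#' describe a phenotype or patient group.  Citations co-sentential with
#' a match are blacklisted from discovery-citation selection.
#'
#' @param doc an \code{\link{analyze_text}} result.
#' @return data.frame with \code{start_index}, \code{end_index} (token
#'   index range of the matched sequence) and \code{sentence_index}.
#' @export
match_exclusion_pattern <- function(doc) {
  tk <- doc$tokens
  out <- data.frame(start_index = integer(), end_index = integer(),
                    sentence_index = integer())
  if (nrow(tk) == 0L) return(out)
  advs <- which(tk$pos == "ADV" & tk$dep == "advmod")
  rows <- list()
  for (ad in advs) {
    v <- tk$head[ad] + 1L
    if (tk$pos[v] != "VERB") next
    sent <- tk$sentence_index[v]
    preps <- .children(tk, tk$index[v])
    preps <- preps[tk$pos[preps] == "ADP" & tk$dep[preps] == "prep" &
                   tk$sentence_index[preps] == sent]
    for (pp in preps) {
      pk <- .children(tk, tk$index[pp])
      num <- pk[tk$pos[pk] == "NUM"]                 # "reported in 4"
      if (!length(num)) {
        objs <- pk[tk$pos[pk] %in% c("NOUN", "PROPN")]
        for (ob in objs) {
          ok <- .children(tk, tk$index[ob])
          num <- c(num, ok[tk$pos[ok] == "NUM" & tk$dep[ok] == "nummod"])
        }
      }
      if (length(num)) {
        span <- range(c(ad, v, pp, num))
        rows[[length(rows) + 1L]] <- data.frame(
          start_index = tk$index[span[1]], end_index = tk$index[span[2]],
          sentence_index = sent)
        break
      }
    }
  }
  if (length(rows)) unique(do.call(rbind, rows)) else out
}

#' Detect model-organism mentions
#'
#' One mention per lexicon token with nominal part of speech (common or
#' proper noun); duplicate mentions of a species within a sentence are
#' collapsed to the first.
#'
#' @param doc an \code{\link{analyze_text}} result.
#' @param lexicon species lexicon
#'   (default \code{\link{default_species_lexicon}}).
#' @return data.frame with \code{species}, \code{token_index},
#'   \code{sentence_index}.
#' @export
detect_organisms <- function(doc, lexicon = default_species_lexicon()) {
  tk <- doc$tokens
  map <- species_surface_map(lexicon)
  out <- data.frame(species = character(), token_index = integer(),
                    sentence_index = integer(), stringsAsFactors = FALSE)
  if (nrow(tk) == 0L) return(out)
  nominal <- tk$pos %in% c("NOUN", "PROPN")
  key <- map[tk$lemma]
  key[is.na(key)] <- map[tolower(tk$text)][is.na(key)]
  hit <- which(nominal & !is.na(key))
  if (!length(hit)) return(out)
  res <- data.frame(species = unname(key[hit]), token_index = tk$index[hit],
                    sentence_index = tk$sentence_index[hit],
                    stringsAsFactors = FALSE)
  res <- res[!duplicated(res[, c("species", "sentence_index")]), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}
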