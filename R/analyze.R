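# Deterministic rule-based linguistic analyzer.
#
# The analyzer provides the substrate every pattern consumes: tokens
# with surface, lemma, universal POS tag, dependency relation, head
# index, sentence index and character span.  It is intentionally a
# small, fully deterministic engine: lexicon-driven tagging plus a
# fixed head-assignment procedure rich enough to represent the
# attachment geometries the cohort/exclusion patterns are defined over
# (nummod, amod, det, advmod, aux, prep, pobj, nsubj/obj, conj).
# Citation marks are pre-chunked into atomic tokens so that periods and
# years inside them never split sentences.

.pos_det <- c("the", "a", "an", "this", "these", "that", "those", "both",
              "each", "every", "another", "no", "any", "some", "several",
              "many", "few", "most", "all", "her", "his", "their", "its",
              "our", "such")
.pos_adp <- c("in", "of", "with", "from", "by", "to", "for", "on", "at",
              "among", "within", "during", "after", "before", "between",
              "into", "through", "under", "without", "via", "as", "per",
              "despite", "over")
.pos_aux <- c("was", "were", "is", "are", "be", "been", "being", "has",
              "have", "had", "could", "can", "may", "might", "would",
              "will", "should", "must", "did", "does", "do")
.pos_pron <- c("they", "we", "he", "she", "it", "i", "you", "who", "whom",
               "which", "them", "him", "us")
.pos_cconj <- c("and", "or", "but", "nor")
.pos_sconj <- c("because", "although", "while", "whereas", "if", "when",
                "since", "that", "whether")
.pos_adv_lex <- c("previously", "originally", "initially", "also", "first",
                  "subsequently", "later", "earlier", "independently",
                  "simultaneously", "only", "further", "then", "thus",
                  "however", "moreover", "furthermore", "respectively",
                  "formerly", "once", "again", "not", "never", "already")

# -ly words that are not adverbs (the suffix heuristic must skip these)
.not_adverbs <- c("family", "families", "anomaly", "anomalies", "assembly",
                  "assemblies", "supply", "reply", "apply", "italy",
                  "butterfly", "monopoly", "july")

.adj_lex <- c("unrelated", "affected", "unaffected", "novel", "de", "novo",
              "consanguineous", "homozygous", "heterozygous", "compound",
              "additional", "separate", "distinct", "large", "small", "new",
              "independent", "primary", "secondary", "clinical", "same",
              "similar", "severe", "mild", "autosomal", "recessive",
              "dominant", "pathogenic", "causal", "causative", "genetic",
              "molecular", "functional", "early", "late", "different",
              "comparable", "possible", "responsible", "available",
              "sporadic", "familial", "truncating", "missense", "biallelic",
              "knockout", "mutant", "wildtype", "normal", "reduced",
              "abnormal", "developmental", "embryonic", "human", "adult")

.verb_lex <- c("identify", "report", "describe", "find", "study", "observe",
               "detect", "screen", "sequence", "perform", "demonstrate",
               "show", "confirm", "establish", "associate", "carry",
               "harbor", "localize", "display", "develop", "use", "exhibit",
               "reveal", "map", "note", "delineate", "analyze", "ascertain",
               "recruit", "link", "make", "comprise", "generate", "model",
               "segregate", "present", "involve", "cause", "result",
               "suggest", "examine", "include", "restore", "rescue",
               "abolish", "express", "mutate", "underlie", "affect",
               "characterize", "evaluate", "investigate", "publish",
               "diagnose", "follow", "refer", "occur", "remain", "lead",
               "encode", "produce", "replicate", "verify", "substantiate")

.irregular_verbs <- c(found = "find", made = "make", shown = "show",
                      showed = "show", underwent = "undergo", led = "lead",
                      born = "bear", arose = "arise", gave = "give",
                      took = "take", saw = "see", studied = "study",
                      carried = "carry")

.irregular_nouns <- c(mice = "mouse", children = "child", women = "woman",
                      men = "man", people = "people", feet = "foot",
                      teeth = "tooth", sheep = "sheep", cattle = "cattle",
                      flies = "fly", analyses = "analysis",
                      families = "family", studies = "study",
                      series = "series", fetuses = "fetus",
                      sibs = "sib", yeasts = "yeast")

# --- tokenization ----------------------------------------------------------

.cite_brace_re <- "\\{[0-9]+(?:[ ]?,[ ]?[0-9]+)*:[^{}]*\\}"
.cite_surface_re <- paste0(
  "[A-Z][A-Za-z'-]+",
  "(?: (?:and|&) [A-Z][A-Za-z'-]+)?",
  "(?:,? et al\\.?)?",
  " \\([0-9]{4}\\)")
.word_re <- "[A-Za-z][A-Za-z0-9]*(?:-[A-Za-z0-9]+)*|[0-9]+(?:,[0-9]{3})*|[0-9]+|[^[:space:]]"

.regex_spans <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Tokenize into a data.frame of (text, start, end, is_citation); spans are
# 0-based half-open character offsets into `text`.
tokenize_text <- function(text) {
  empty <- data.frame(text = character(), start = integer(),
                      end = integer(), is_citation = logical())
  if (is.na(text) || !nzchar(text)) return(empty)
  n <- nchar(text)
  taken <- logical(n)
  toks <- list()
  add_spans <- function(spans, is_cite) {
    if (is.null(spans)) return()
    for (i in seq_len(nrow(spans))) {
      s <- spans$start[i]; e <- spans$end[i]
      if (any(taken[(s + 1L):e])) next
      taken[(s + 1L):e] <<- TRUE
      toks[[length(toks) + 1L]] <<- data.frame(
        text = substr(text, s + 1L, e), start = s, end = e,
        is_citation = is_cite)
    }
  }
  add_spans(.regex_spans(text, .cite_brace_re), TRUE)
  add_spans(.regex_spans(text, .cite_surface_re), TRUE)
  # Tokenize the untaken stretches.
  free <- rle(taken)
  pos <- 0L
  for (i in seq_along(free$lengths)) {
    len <- free$lengths[i]
    if (!free$values[i]) {
      seg <- substr(text, pos + 1L, pos + len)
      spans <- .regex_spans(seg, .word_re)
      if (!is.null(spans)) {
        spans$start <- spans$start + pos
        spans$end <- spans$end + pos
        add_spans(spans, FALSE)
      }
    }
    pos <- pos + len
  }
  out <- do.call(rbind, toks)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- lemmatization ---------------------------------------------------------

verb_lemma <- function(w) {
  if (w %in% names(.irregular_verbs)) return(unname(.irregular_verbs[w]))
  cand <- unique(c(
    w,
    if (endsWith(w, "ies")) paste0(substr(w, 1, nchar(w) - 3L), "y"),
    if (endsWith(w, "ied")) paste0(substr(w, 1, nchar(w) - 3L), "y"),
    if (endsWith(w, "es")) substr(w, 1, nchar(w) - 2L),
    if (endsWith(w, "ed")) substr(w, 1, nchar(w) - 2L),
    if (endsWith(w, "ed")) substr(w, 1, nchar(w) - 1L),
    if (endsWith(w, "ed") && nchar(w) > 4L &&
        substr(w, nchar(w) - 2L, nchar(w) - 2L) ==
        substr(w, nchar(w) - 3L, nchar(w) - 3L))
      substr(w, 1, nchar(w) - 3L),
    if (endsWith(w, "ing")) substr(w, 1, nchar(w) - 3L),
    if (endsWith(w, "ing")) paste0(substr(w, 1, nchar(w) - 3L), "e"),
    if (endsWith(w, "s") && !endsWith(w, "ss")) substr(w, 1, nchar(w) - 1L)
  ))
  hit <- cand[cand %in% .verb_lex]
  if (length(hit)) hit[1] else NA_character_
}

noun_lemma <- function(w) {
  if (w %in% names(.irregular_nouns)) return(unname(.irregular_nouns[w]))
  if (endsWith(w, "ies") && nchar(w) > 4L)
    return(paste0(substr(w, 1, nchar(w) - 3L), "y"))
  if (grepl("(ches|shes|xes|sses|zes)$", w))
    return(substr(w, 1, nchar(w) - 2L))
  if (endsWith(w, "s") && !endsWith(w, "ss") && !endsWith(w, "us") &&
      !endsWith(w, "is") && nchar(w) > 3L)
    return(substr(w, 1, nchar(w) - 1L))
  w
}

# --- tagging ---------------------------------------------------------------

.tag_tokens <- function(tok, sent_start, species_surfaces) {
  n <- nrow(tok)
  pos <- character(n)
  lemma <- character(n)
  for (i in seq_len(n)) {
    tx <- tok$text[i]
    lo <- tolower(tx)
    if (tok$is_citation[i]) {
      pos[i] <- "X"; lemma[i] <- tx; next
    }
    if (grepl("^[0-9]", tx)) {
      pos[i] <- "NUM"; lemma[i] <- lo; next
    }
    if (!grepl("^[A-Za-z]", tx)) {
      pos[i] <- "PUNCT"; lemma[i] <- tx; next
    }
    vl <- NULL
    if (lo %in% .pos_det) pos[i] <- "DET"
    else if (lo %in% .pos_adp) pos[i] <- "ADP"
    else if (lo %in% .pos_aux) pos[i] <- "AUX"
    else if (lo %in% .pos_pron) pos[i] <- "PRON"
    else if (lo %in% .pos_cconj) pos[i] <- "CCONJ"
    else if (is_cardinal(lo)) pos[i] <- "NUM"
    else if (lo %in% .adj_lex) pos[i] <- "ADJ"
    else if (lo %in% .pos_adv_lex ||
             (endsWith(lo, "ly") && nchar(lo) > 3L &&
              !lo %in% .not_adverbs)) pos[i] <- "ADV"
    else if (!is.na(vl <- verb_lemma(lo)) && !sent_start[i]) pos[i] <- "VERB"
    else if (lo %in% species_surfaces) pos[i] <- "NOUN"
    else if (grepl("^[A-Z0-9-]+$", tx) && nchar(tx) >= 2L) pos[i] <- "PROPN"
    else if (grepl("^[A-Z]", tx) && !sent_start[i]) pos[i] <- "PROPN"
    else pos[i] <- "NOUN"
    lemma[i] <- switch(pos[i],
      VERB = vl,
      NOUN = noun_lemma(lo),
      PROPN = noun_lemma(lo),
      lo)
  }
  # Sentence-initial verbs ("Identified..." is rare in this prose) stay
  # nouns unless the noun reading is impossible; acceptable for the domain.
  list(pos = pos, lemma = lemma)
}

# --- dependency assignment -------------------------------------------------

# Assign heads and relations within one sentence (indices are positions in
# the full token table).  Deterministic approximation of the universal
# dependencies needed by the patterns.
.parse_sentence <- function(pos, idx) {
  n <- length(idx)
  head <- integer(n)
  dep <- character(n)
  p <- pos[idx]
  verbs <- which(p == "VERB")
  root <- if (length(verbs)) verbs[1] else {
    aux <- which(p == "AUX")
    if (length(aux)) aux[1] else {
      nonp <- which(p != "PUNCT")
      if (length(nonp)) nonp[1] else 1L
    }
  }
  prev_word <- function(i) {
    j <- i - 1L
    while (j >= 1L && p[j] == "PUNCT") j <- j - 1L
    if (j >= 1L) j else NA_integer_
  }
  nearest <- function(i, cands) {
    if (!length(cands)) return(NA_integer_)
    cands[which.min(abs(cands - i))]
  }
  next_nominal <- function(i, skip, maxhop = 4L) {
    j <- i + 1L; hops <- 0L
    while (j <= n && hops < maxhop) {
      if (p[j] %in% c("NOUN", "PROPN")) return(j)
      if (!(p[j] %in% skip)) return(NA_integer_)
      j <- j + 1L; hops <- hops + 1L
    }
    NA_integer_
  }
  for (i in seq_len(n)) {
    if (i == root) { head[i] <- i; dep[i] <- "ROOT"; next }
    head[i] <- root
    dep[i] <- "dep"
    if (p[i] == "VERB") {
      dep[i] <- "conj"
    } else if (p[i] == "AUX") {
      fol <- verbs[verbs > i]
      head[i] <- if (length(fol)) fol[1] else root
      dep[i] <- "aux"
    } else if (p[i] == "ADV") {
      v <- nearest(i, verbs)
      if (!is.na(v)) head[i] <- v
      dep[i] <- "advmod"
    } else if (p[i] == "ADP") {
      pw <- prev_word(i)
      if (!is.na(pw) && p[pw] %in% c("NOUN", "PROPN", "NUM")) {
        head[i] <- pw
      } else {
        pv <- verbs[verbs < i]
        head[i] <- if (length(pv)) pv[length(pv)] else root
      }
      dep[i] <- "prep"
    } else if (p[i] == "NUM") {
      nn <- next_nominal(i, skip = c("ADJ", "DET"))
      pw <- prev_word(i)
      if (!is.na(nn)) {
        head[i] <- nn; dep[i] <- "nummod"
      } else if (!is.na(pw) && p[pw] == "ADP") {
        head[i] <- pw; dep[i] <- "pobj"
      } else {
        dep[i] <- "obl"
      }
    } else if (p[i] == "ADJ") {
      nn <- next_nominal(i, skip = c("ADJ", "NUM", "DET"))
      if (!is.na(nn)) { head[i] <- nn; dep[i] <- "amod" }
      else dep[i] <- "amod"
    } else if (p[i] == "DET") {
      nn <- next_nominal(i, skip = c("ADJ", "NUM"))
      if (!is.na(nn)) { head[i] <- nn; dep[i] <- "det" }
      else dep[i] <- "det"
    } else if (p[i] %in% c("NOUN", "PROPN", "PRON")) {
      # governing adposition: nearest preceding ADP with no other
      # nominal in between
      j <- i - 1L; gov <- NA_integer_
      while (j >= 1L) {
        if (p[j] %in% c("NOUN", "PROPN", "PRON", "VERB", "X")) break
        if (p[j] == "ADP") { gov <- j; break }
        j <- j - 1L
      }
      if (!is.na(gov)) { head[i] <- gov; dep[i] <- "pobj" }
      else if (i < root) dep[i] <- "nsubj"
      else dep[i] <- "obj"
    } else if (p[i] == "PUNCT") {
      dep[i] <- "punct"
    } else if (p[i] == "CCONJ") {
      dep[i] <- "cc"
    } else if (p[i] == "X") {
      dep[i] <- "cite"
    }
  }
  list(head = idx[head], dep = dep)
}

# --- public API ------------------------------------------------------------

#' Analyze a paragraph of text
#'
#' Runs the deterministic rule-based engine: tokenization (citation
#' marks kept atomic), sentence segmentation, lexicon POS tagging,
#' lemmatization and head assignment.  The result is the substrate for
#' all pattern matching.
#'
#' @param paragraph character scalar of plain text.
#' @return an object of class \code{analyzed_doc}: a list with
#'   \code{text}, \code{tokens} (data.frame with 0-based \code{index},
#'   \code{text}, \code{lemma}, \code{pos}, \code{dep}, \code{head},
#'   \code{sentence_index}, \code{start}, \code{end},
#'   \code{is_citation}) and \code{sentence_count}.
#' @examples
#' doc <- analyze_text("Mice were studied. Variants were found.")
#' doc$sentence_count
#' @export
analyze_text <- function(paragraph) {
  stopifnot(is.character(paragraph), length(paragraph) == 1L)
  tok <- tokenize_text(paragraph)
  if (nrow(tok) == 0L) {
    doc <- list(text = paragraph,
                tokens = data.frame(index = integer(), text = character(),
                                    lemma = character(), pos = character(),
                                    dep = character(), head = integer(),
                                    sentence_index = integer(),
                                    start = integer(), end = integer(),
                                    is_citation = logical()),
                sentence_count = 0L)
    class(doc) <- "analyzed_doc"
    return(doc)
  }
  n <- nrow(tok)
  # sentence segmentation: plain ".", "!", "?" tokens end a sentence
  sent <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    sent[i] <- cur
    if (!tok$is_citation[i] && tok$text[i] %in% c(".", "!", "?")) {
      if (i < n) cur <- cur + 1L
    }
  }
  sent_start <- c(TRUE, sent[-1L] != sent[-n])
  species_surfaces <- names(species_surface_map())
  tg <- .tag_tokens(tok, sent_start, species_surfaces)
  head <- integer(n)
  dep <- character(n)
  for (s in unique(sent)) {
    idx <- which(sent == s)
    pr <- .parse_sentence(tg$pos, idx)
    head[idx] <- pr$head
    dep[idx] <- pr$dep
  }
  tokens <- data.frame(
    index = seq_len(n) - 1L,
    text = tok$text,
    lemma = tg$lemma,
    pos = tg$pos,
    dep = dep,
    head = head - 1L,
    sentence_index = sent,
    start = tok$start,
    end = tok$end,
    is_citation = tok$is_citation,
    stringsAsFactors = FALSE)
  doc <- list(text = paragraph, tokens = tokens,
              sentence_count = length(unique(sent)))
  class(doc) <- "analyzed_doc"
  doc
}

#' @export
print.analyzed_doc <- function(x, ...) {
  cat(sprintf("<analyzed_doc> %d tokens, %d sentence(s)\n",
              nrow(x$tokens), x$sentence_count))
  cat(strtrim(x$text, 70), if (nchar(x$text) > 70) "..." else "", "\n")
  invisible(x)
}

# character span of each sentence: data.frame(sentence_index, start, end)
sentence_spans <- function(doc) {
  tk <- doc$tokens
  if (nrow(tk) == 0L)
    return(data.frame(sentence_index = integer(), start = integer(),
                      end = integer()))
  agg_s <- tapply(tk$start, tk$sentence_index, min)
  agg_e <- tapply(tk$end, tk$sentence_index, max)
  data.frame(sentence_index = as.integer(names(agg_s)),
             start = as.integer(agg_s), end = as.integer(agg_e))
}
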