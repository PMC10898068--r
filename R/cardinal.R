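# Cardinal-number normalization: digit strings (with thousands
# separators) and English cardinal words/compounds up to 999.

.card_units <- c(
  one = 1, two = 2, three = 3, four = 4, five = 5, six = 6, seven = 7,
  eight = 8, nine = 9
)
.card_teens <- c(
  ten = 10, eleven = 11, twelve = 12, thirteen = 13, fourteen = 14,
  fifteen = 15, sixteen = 16, seventeen = 17, eighteen = 18, nineteen = 19
)
.card_tens <- c(
  twenty = 20, thirty = 30, forty = 40, fifty = 50, sixty = 60,
  seventy = 70, eighty = 80, ninety = 90
)
.card_words <- c(.card_units, .card_teens, .card_tens)

.numeral_error <- function(surface) {
  stop(structure(
    class = c("gdamine_numeral_error", "error", "condition"),
    list(message = sprintf("cannot normalize numeral '%s'", surface),
         call = sys.call(-1))
  ))
}

#' Normalize a cardinal numeral to an integer
#'
#' Maps digit strings (optionally with comma thousands separators) and
#' English cardinal words or hyphen/space compounds up to 999 (e.g.
#' "twenty-three", "two hundred forty-five") to their integer value.
#'
#' @param token_surface character scalar, the numeral as written.
#' @return integer scalar.
#' @examples
#' normalize_cardinal("two")          # 2
#' normalize_cardinal("1,204")        # 1204
#' normalize_cardinal("twenty-three") # 23
#' @export
normalize_cardinal <- function(token_surface) {
  if (!is.character(token_surface) || length(token_surface) != 1L ||
      is.na(token_surface)) {
    .numeral_error(paste(token_surface, collapse = " "))
  }
  s <- trimws(token_surface)
  if (grepl("^[0-9]+(,[0-9]{3})*$", s) || grepl("^[0-9]+$", s)) {
    v <- suppressWarnings(as.numeric(gsub(",", "", s)))
    if (is.na(v)) .numeral_error(s)
    return(as.integer(v))
  }
  toks <- strsplit(tolower(s), "[ -]+")[[1]]
  toks <- toks[toks != "and" & nzchar(toks)]
  if (length(toks) == 0L) .numeral_error(s)
  val <- 0L
  seen <- FALSE
  for (tk in toks) {
    if (tk == "hundred") {
      if (!seen) val <- 1L
      val <- val * 100L
      seen <- TRUE
    } else if (tk %in% names(.card_words)) {
      val <- val + as.integer(.card_words[[tk]])
      seen <- TRUE
    } else {
      .numeral_error(s)
    }
  }
  if (!seen || val < 1L || val > 999L) .numeral_error(s)
  val
}

# Internal: TRUE when the surface is a normalizable numeral.
is_cardinal <- function(surface) {
  !inherits(tryCatch(normalize_cardinal(surface),
                     gdamine_numeral_error = function(e) e),
            "gdamine_numeral_error")
}
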