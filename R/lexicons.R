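# Configurable lexicons: species surfaces and cohort anchor lemmas ship
# as YAML under inst/extdata so users can audit and extend them without
# touching code.

#' Default model-organism lexicon
#'
#' Loads the species lexicon shipped with the package: a named list
#' mapping canonical species keys to the surface lemmas accepted as
#' nominal mentions.
#'
#' @param path optional path to an alternative YAML lexicon.
#' @return named list of character vectors.
#' @export
default_species_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.gdamine_env$species)) return(.gdamine_env$species)
    path <- system.file("extdata", "species.yaml", package = "gdamine")
    lex <- yaml::read_yaml(path)
    lex <- lapply(lex, as.character)
    .gdamine_env$species <- lex
    return(lex)
  }
  lapply(yaml::read_yaml(path), as.character)
}

#' Default cohort anchor-noun lemmas
#'
#' Loads the anchor-lemma set shipped with the package (patient, family,
#' individual, ... plus sibling/sib/proband/kindred).
#'
#' @param path optional path to an alternative YAML file with an
#'   \code{anchors} key.
#' @return character vector of lemmas.
#' @export
default_anchor_lemmas <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.gdamine_env$anchors)) return(.gdamine_env$anchors)
    path <- system.file("extdata", "anchors.yaml", package = "gdamine")
    a <- as.character(yaml::read_yaml(path)$anchors)
    .gdamine_env$anchors <- a
    return(a)
  }
  as.character(yaml::read_yaml(path)$anchors)
}

# Flat surface -> species key map, lowercased.
species_surface_map <- function(lexicon = default_species_lexicon()) {
  keys <- rep(names(lexicon), lengths(lexicon))
  surfaces <- tolower(unlist(lexicon, use.names = FALSE))
  stats::setNames(keys, surfaces)
}
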