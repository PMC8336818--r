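# Lexical tagging (layer 2): 13 semantic categories from plain-text
# lexicons, matched on lemma or surface, case-insensitively, longest match
# first.  The shipped lexicons are a reconstruction seeded from the
# published example terms and are meant to be extended via configuration.

#' The 13 semantic categories
#' @export
lexicon_categories <- function() {
  c("SH", "BODY_PART", "HARM_ACTION", "FAMILY", "HEDGING", "INTENT",
    "MED", "MODALITY", "NEGATION", "R_SPEECH", "LIFE_STAGE", "PAST",
    "PRESENT")
}

#' Load the semantic lexicons
#'
#' Reads one file per category from \code{directory}
#' (\code{<CATEGORY>.txt}, one term per line, \code{#} comments).  Terms
#' are normalised to lower case; multi-word terms are allowed and matched
#' as token sequences.
#'
#' @param directory Directory holding the 13 lexicon files.  Defaults to
#'   the reconstruction shipped with the package.
#' @return A named list of class \code{sh_lexicons}: one character vector
#'   of terms per category.
#' @export
load_lexicons <- function(directory = system.file("extdata", "lexicons",
                                                  package = "perisharm")) {
  cats <- lexicon_categories()
  files <- file.path(directory, paste0(cats, ".txt"))
  missing <- cats[!file.exists(files)]
  if (length(missing)) {
    stop("missing lexicon file(s) for category: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lex <- lapply(files, function(f) {
    x <- readLines(f, warn = FALSE, encoding = "UTF-8")
    x <- sub("#.*$", "", x)
    x <- tolower(trimws(x))
    unique(x[nzchar(x)])
  })
  names(lex) <- cats
  empty <- cats[vapply(lex, length, 1L) == 0L]
  if (length(empty)) {
    stop("empty lexicon for category: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  structure(lex, class = "sh_lexicons")
}

#' @export
print.sh_lexicons <- function(x, ...) {
  cat(sprintf("<sh_lexicons: %d categories, %d terms>\n",
              length(x), sum(vapply(x, length, 1L))))
  invisible(x)
}

# Split lexicon terms into word sequences with the same tokeniser the
# documents use, so multi-part terms line up with token boundaries.
.term_words <- function(term, exceptions) {
  tolower(tokenize_text(term, exceptions)$surface)
}

#' Tag tokens with semantic categories
#'
#' Every maximal token sequence whose surface or lemma sequence matches a
#' lexicon term (case-insensitively) receives one semantic tag.  Longer
#' matches suppress shorter matches they strictly contain; equal-length
#' matches from different categories coexist on the same span.  Existing
#' tags are replaced, so the operation is idempotent.
#'
#' @param doc An \code{sh_document} from \code{\link{preprocess}}.
#' @param lexicons An \code{sh_lexicons} from \code{\link{load_lexicons}}.
#' @param exceptions Tokenisation exceptions (used to split multi-word
#'   lexicon terms consistently with document tokenisation).
#' @return The document with its \code{tags} data.frame populated
#'   (columns \code{start}, \code{end} token ids and \code{category}).
#' @export
tag_semantics <- function(doc, lexicons,
                          exceptions = read_token_exceptions()) {
  stopifnot(inherits(doc, "sh_document"), inherits(lexicons, "sh_lexicons"))
  n <- nrow(doc$tokens)
  surf <- tolower(doc$tokens$surface)
  lem <- tolower(doc$tokens$lemma)
  cand <- list()
  for (cat in names(lexicons)) {
    for (term in lexicons[[cat]]) {
      words <- .term_words(term, exceptions)
      k <- length(words)
      if (k == 0L || k > n) next
      if (k == 1L) {
        hits <- which(surf == words | lem == words)
        for (h in hits) cand[[length(cand) + 1L]] <- c(h, h, match(cat, names(lexicons)))
      } else {
        for (i in seq_len(n - k + 1L)) {
          idx <- i:(i + k - 1L)
          if (all(surf[idx] == words | lem[idx] == words)) {
            cand[[length(cand) + 1L]] <- c(i, i + k - 1L, match(cat, names(lexicons)))
          }
        }
      }
    }
  }
  if (!length(cand)) {
    doc$tags <- data.frame(start = integer(0), end = integer(0),
                           category = character(0), stringsAsFactors = FALSE)
    return(doc)
  }
  m <- do.call(rbind, cand)
  tags <- data.frame(start = m[, 1L], end = m[, 2L],
                     category = names(lexicons)[m[, 3L]],
                     stringsAsFactors = FALSE)
  tags <- unique(tags)
  # longest match wins: drop tags strictly contained in a longer tag that
  # overlaps them
  len <- tags$end - tags$start
  keep <- rep(TRUE, nrow(tags))
  for (i in seq_len(nrow(tags))) {
    longer <- which(len > len[i] & tags$start <= tags$end[i] &
                      tags$end >= tags$start[i])
    if (length(longer)) keep[i] <- FALSE
  }
  tags <- tags[keep, , drop = FALSE]
  tags <- tags[order(tags$start, tags$end, tags$category), , drop = FALSE]
  rownames(tags) <- NULL
  doc$tags <- tags
  doc
}

# Category membership per token: character vector of categories covering
# token id i.
.token_categories <- function(doc, i) {
  t <- doc$tags
  t$category[t$start <= i & t$end >= i]
}
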