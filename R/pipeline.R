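# End-to-end pipeline: the five processing layers in sequence.

#' Annotate a single clinical note
#'
#' Runs the full pipeline on one note: linguistic preprocessing, lexical
#' tagging, mention detection with exclusions, and attribute resolution
#' (dependency negation, contextual search, history sections).
#'
#' @param text Note text.
#' @param user_id,doc_id Identifiers.
#' @param lexicons,rules,headers,exceptions Pipeline resources; default to
#'   the versions shipped with the package.
#' @param config Configuration from \code{\link{sh_config}}.
#' @return Fully annotated \code{sh_document}.
#' @examples
#' doc <- annotate_note("She took an overdose last night.", "u1", "d1")
#' doc$mentions
#' @export
annotate_note <- function(text, user_id = "u", doc_id = "d",
                          lexicons = load_lexicons(),
                          rules = load_rules(),
                          headers = read_history_headers(),
                          exceptions = read_token_exceptions(),
                          config = sh_config()) {
  doc <- preprocess(text, user_id = user_id, doc_id = doc_id,
                    exceptions = exceptions)
  doc <- tag_semantics(doc, lexicons, exceptions = exceptions)
  doc <- detect_mentions(doc, rules)
  doc <- apply_exclusions(doc, rules)
  sections <- detect_history_sections(doc, headers)
  resolve_attributes(doc, config, sections)
}

#' Annotate a corpus of notes
#'
#' @param corpus data.frame with columns \code{doc_id}, \code{user_id},
#'   \code{text} (see \code{\link{read_corpus}}).
#' @inheritParams annotate_note
#' @return List of annotated \code{sh_document} objects, one per row.
#' @export
annotate_corpus <- function(corpus,
                            lexicons = load_lexicons(),
                            rules = load_rules(),
                            headers = read_history_headers(),
                            exceptions = read_token_exceptions(),
                            config = sh_config()) {
  stopifnot(is.data.frame(corpus),
            all(c("doc_id", "user_id", "text") %in% names(corpus)))
  lapply(seq_len(nrow(corpus)), function(i) {
    annotate_note(corpus$text[i], user_id = corpus$user_id[i],
                  doc_id = corpus$doc_id[i], lexicons = lexicons,
                  rules = rules, headers = headers,
                  exceptions = exceptions, config = config)
  })
}

#' Mention table of an annotated corpus
#'
#' @param docs List of annotated documents.
#' @return data.frame with one row per mention: \code{doc_id},
#'   \code{user_id}, \code{char_start}, \code{char_end} (0-based,
#'   half-open), \code{text}, \code{status}, \code{temporality},
#'   \code{polarity}, \code{rule}.
#' @export
mention_table <- function(docs) {
  if (inherits(docs, "sh_document")) docs <- list(docs)
  rows <- lapply(docs, function(d) {
    m <- d$mentions
    if (!nrow(m)) return(NULL)
    data.frame(doc_id = d$doc_id, user_id = d$user_id,
               char_start = m$char_start, char_end = m$char_end,
               text = substring(d$text, m$char_start + 1L, m$char_end),
               status = m$status, temporality = m$temporality,
               polarity = m$polarity, rule = m$rule,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(doc_id = character(0), user_id = character(0),
                      char_start = integer(0), char_end = integer(0),
                      text = character(0), status = character(0),
                      temporality = character(0), polarity = character(0),
                      rule = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
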