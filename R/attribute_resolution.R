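# Attribute resolution (layers 4 and 5): dependency-based negation for
# polarity, and a windowed contextual search for status and temporality,
# plus symbol negation and the history-section override.
#
# Defaults follow the coding rules: a mention with no cue in context is
# (relevant, current, positive).

#' Pipeline configuration defaults
#'
#' @param window_width Context half-width in tokens (default 10).
#' @param sentence_bounded_window Truncate the context window at sentence
#'   boundaries (default \code{FALSE}).
#' @param paper_faithful_mode When \code{TRUE}, any trailing modality cue
#'   in the window demotes a mention to non-relevant; the default
#'   (\code{FALSE}) only lets a trailing modal demote the mention when its
#'   syntactic scope plausibly covers it (so \dQuote{she thought the
#'   self-harm would kill her} stays relevant).
#' @param emit_uncertain Reserved: the data model admits an
#'   \code{uncertain} status but no shipped rule emits it.
#' @param heuristic_k Minimum number of true mentions for user-level
#'   flagging (default 2).
#' @param span_match_mode Default span-matching criterion for evaluation.
#' @param distinct_documents Require the \code{heuristic_k} true mentions
#'   to occur in distinct documents (default \code{FALSE}).
#' @return Named list of configuration values.
#' @export
sh_config <- function(window_width = 10L,
                      sentence_bounded_window = FALSE,
                      paper_faithful_mode = FALSE,
                      emit_uncertain = FALSE,
                      heuristic_k = 2L,
                      span_match_mode = c("exact", "overlap"),
                      distinct_documents = FALSE) {
  stopifnot(window_width >= 0L, heuristic_k >= 1L)
  list(window_width = as.integer(window_width),
       sentence_bounded_window = isTRUE(sentence_bounded_window),
       paper_faithful_mode = isTRUE(paper_faithful_mode),
       emit_uncertain = isTRUE(emit_uncertain),
       heuristic_k = as.integer(heuristic_k),
       span_match_mode = match.arg(span_match_mode),
       distinct_documents = isTRUE(distinct_documents))
}

# Tokens of the mention whose head lies outside the span (the span root;
# first such token if several).
.mention_root <- function(doc, start, end) {
  span <- start:end
  hd <- doc$tokens$head_id[span]
  cand <- span[!(hd %in% span) | hd == span]  # head outside, or sentence root
  if (length(cand)) cand[1L] else start
}

# Ancestors of token i by head links, within its sentence, up to `max_up`.
.ancestors <- function(doc, i, max_up = 8L) {
  out <- integer(0)
  cur <- i
  for (k in seq_len(max_up)) {
    h <- doc$tokens$head_id[cur]
    if (is.na(h) || h == cur) break
    out <- c(out, h)
    cur <- h
  }
  out
}

.children <- function(doc, i) which(doc$tokens$head_id == i &
                                      seq_len(nrow(doc$tokens)) != i)

.governs_neg <- function(doc, i) {
  kids <- .children(doc, i)
  any(doc$tokens$dep[kids] == "neg")
}

.is_tagged <- function(doc, i, category) {
  category %in% .token_categories(doc, i)
}

.neg_symbols <- c("x", "✗", "✘", "nil", "0", "none", "no")

#' Resolve mention polarity
#'
#' A mention is negative when any of the following holds, otherwise
#' positive:
#' \enumerate{
#'   \item a token of the mention governs a \code{neg} dependency
#'     (\dQuote{she did not cut herself});
#'   \item the mention's governor is a reported-speech verb that is itself
#'     negated (\dQuote{she did not report harming herself});
#'   \item the mention is governed, directly or via its head chain, by a
#'     NEGATION-tagged word or by a word that governs a \code{neg}
#'     dependency (\dQuote{she denies any self-harm}, \dQuote{no history
#'     of suicide});
#'   \item symbol negation: the mention is followed on its line by a colon
#'     and a negation symbol (\dQuote{Suicide attempts: X}).
#' }
#'
#' @param doc Annotated document (parsed and tagged).
#' @param start,end Token span of the mention.
#' @return \code{"negative"} or \code{"positive"}.
#' @export
resolve_polarity <- function(doc, start, end) {
  tk <- doc$tokens
  span <- start:end
  # (a) a span token heads a neg dependency
  for (i in span) if (.governs_neg(doc, i)) return("negative")
  root <- .mention_root(doc, start, end)
  gov <- tk$head_id[root]
  # (b) negated reported-speech governor
  if (!is.na(gov) && gov != root && .is_tagged(doc, gov, "R_SPEECH")) {
    gg <- tk$head_id[gov]
    if (.governs_neg(doc, gov) ||
        (!is.na(gg) && gg != gov && .is_tagged(doc, gg, "NEGATION"))) {
      return("negative")
    }
  }
  # (c) negation in the governing chain
  anc <- setdiff(.ancestors(doc, root), span)
  for (g in anc) {
    if (.is_tagged(doc, g, "NEGATION")) return("negative")
    if (.governs_neg(doc, g)) return("negative")
  }
  # (d) symbol negation: "<mention>: X" on one line
  n <- nrow(tk)
  if (end + 2L <= n) {
    i1 <- end + 1L; i2 <- end + 2L
    same_line <- !grepl("\n", substr(doc$text, tk$char_end[end] + 1L,
                                     tk$char_start[i2]), fixed = TRUE)
    if (same_line && tk$surface[i1] == ":" &&
        tolower(tk$surface[i2]) %in% .neg_symbols) {
      return("negative")
    }
  }
  "positive"
}

# FAMILY linkage: a FAMILY token within 3 tokens to the left of the span,
# or a FAMILY token that is the subject of the mention's clause verb.
.family_linked <- function(doc, start, end) {
  tk <- doc$tokens
  left <- seq.int(max(1L, start - 3L), max(1L, start - 1L))
  left <- left[left < start]
  for (i in left) if (.is_tagged(doc, i, "FAMILY")) return(TRUE)
  root <- .mention_root(doc, start, end)
  verbs <- c(root, .ancestors(doc, root))
  verbs <- verbs[tk$pos[verbs] %in% c("VERB", "AUX")]
  if (length(verbs)) {
    v <- verbs[1L]
    subj <- which(tk$head_id == v & tk$dep == "nsubj")
    for (s in subj) {
      if (.is_tagged(doc, s, "FAMILY")) return(TRUE)
      # "her mother" with a possessive: check the NP, too
      kids <- .children(doc, s)
      if (any(vapply(kids, function(k) .is_tagged(doc, k, "FAMILY"), TRUE))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Resolve mention status
#'
#' Non-relevant when a HEDGING or MODALITY token lies in the context
#' window, or when the mention is linked to a FAMILY token (a third-party
#' act); relevant otherwise.  HEDGING cues are ignored when the cue word
#' is verbal (\dQuote{she thought that ...} is reported cognition, not
#' ideation).  In the default mode a MODALITY cue after the mention only
#' demotes it when the modal's syntactic scope covers the mention; with
#' \code{paper_faithful_mode = TRUE} any trailing modal in the window
#' demotes it.
#'
#' @inheritParams resolve_polarity
#' @param config Configuration from \code{\link{sh_config}}.
#' @return \code{"relevant"} or \code{"non-relevant"}.
#' @export
resolve_status <- function(doc, start, end, config = sh_config()) {
  tk <- doc$tokens
  if (.family_linked(doc, start, end)) return("non-relevant")
  win <- token_window(doc, c(start, end), config$window_width,
                      config$sentence_bounded_window)
  root <- .mention_root(doc, start, end)
  for (i in win) {
    cats <- .token_categories(doc, i)
    if ("HEDGING" %in% cats && tk$pos[i] != "VERB") return("non-relevant")
    if ("MODALITY" %in% cats) {
      if (i < start) return("non-relevant")
      if (config$paper_faithful_mode) return("non-relevant")
      # trailing modal: only demote when its scope covers the mention
      if (tk$sentence_id[i] != tk$sentence_id[start]) next
      if (tk$pos[i] == "AUX" && tk$dep[i] == "aux") {
        v <- tk$head_id[i]
        if (!is.na(v) && tk$head_id[root] == v && tk$dep[root] == "nsubj") {
          next  # mention is the subject of the modalised clause
        }
      }
      return("non-relevant")
    }
  }
  "relevant"
}

# PAST-like cue positions in the window (LIFE_STAGE counts as past), with
# the chronic-history exception removed.
.past_cues <- function(doc, win) {
  tk <- doc$tokens
  out <- integer(0)
  for (i in win) {
    cats <- .token_categories(doc, i)
    if ("LIFE_STAGE" %in% cats) { out <- c(out, i); next }
    if ("PAST" %in% cats) {
      if (tolower(tk$lemma[i]) %in% c("history", "hx")) {
        prevs <- seq.int(max(1L, i - 2L), max(1L, i - 1L))
        prevs <- prevs[prevs < i]
        if (any(tolower(tk$lemma[prevs]) %in%
                  c("chronic", "longstanding", "long-standing", "ongoing"))) {
          next  # "chronic history of self-harm" is coded current
        }
      }
      out <- c(out, i)
    }
  }
  out
}

#' Resolve mention temporality
#'
#' Historical when the mention lies inside a detected history section, or
#' when a PAST or LIFE_STAGE cue is found in the context window and no
#' PRESENT cue lies nearer to the mention.  Chronic references
#' (\dQuote{chronic history of self-harm}) are coded current, and current
#' is the default in the absence of any cue.
#'
#' @inheritParams resolve_status
#' @param sections History sections from
#'   \code{\link{detect_history_sections}}.
#' @return \code{"historical"} or \code{"current"}.
#' @export
resolve_temporality <- function(doc, start, end, sections = NULL,
                                config = sh_config()) {
  tk <- doc$tokens
  if (!is.null(sections) && nrow(sections)) {
    if (any(sections$start <= start & sections$end >= end)) {
      return("historical")
    }
  }
  win <- token_window(doc, c(start, end), config$window_width,
                      config$sentence_bounded_window)
  past <- .past_cues(doc, win)
  pres <- win[vapply(win, function(i) .is_tagged(doc, i, "PRESENT"), TRUE)]
  if (!length(past)) return("current")
  if (!length(pres)) return("historical")
  dist <- function(i) if (i < start) start - i else i - end
  if (min(vapply(past, dist, 1L)) < min(vapply(pres, dist, 1L))) {
    "historical"           # nearest cue wins; ties fall to current
  } else {
    "current"
  }
}

#' Resolve all mention attributes
#'
#' Runs polarity, status and temporality resolution over every mention of
#' the document.  The three attributes are independent: each reads only
#' the parse, the semantic tags and the history sections.
#'
#' @param doc Document with detected mentions.
#' @param config Configuration from \code{\link{sh_config}}.
#' @param sections History sections; computed from the document when
#'   \code{NULL}.
#' @return Document with mention attributes populated.
#' @export
resolve_attributes <- function(doc, config = sh_config(), sections = NULL) {
  stopifnot(inherits(doc, "sh_document"))
  if (is.null(sections)) sections <- detect_history_sections(doc)
  m <- doc$mentions
  for (r in seq_len(nrow(m))) {
    m$polarity[r] <- resolve_polarity(doc, m$start[r], m$end[r])
    m$status[r] <- resolve_status(doc, m$start[r], m$end[r], config)
    m$temporality[r] <- resolve_temporality(doc, m$start[r], m$end[r],
                                            sections, config)
  }
  doc$mentions <- m
  doc
}
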