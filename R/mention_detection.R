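# Mention detection (layer 3): declarative token-sequence rules create
# self-harm mention spans, exclusion rules cancel false positives, and a
# header grammar marks history sections.
#
# Rule file format (one rule per line):
#   name  priority  action : pattern
# where action is "mention" or "exclude" and the pattern is a sequence of
# whitespace-separated elements.  An element is a set of alternatives
# separated by "|"; an alternative is one or more conditions joined by
# "&"; a condition is key=value[,value...] with keys surface, lemma, pos,
# sem and re (regex on the surface).  Trailing "?" makes an element
# optional, trailing "*" matches 0-3 tokens.  Matching is
# case-insensitive and backtracking.

#' Load a mention rule set
#'
#' @param path Rules file.  Defaults to the reconstructed rule set shipped
#'   with the package.
#' @return List of class \code{sh_rules}; each rule has \code{name},
#'   \code{priority}, \code{action} and a parsed \code{pattern}.
#' @export
load_rules <- function(path = system.file("extdata", "mention_rules.txt",
                                          package = "perisharm")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("rules file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("^\\s*#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  rules <- lapply(lines, .parse_rule_line)
  nm <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate rule name(s): ", paste(unique(nm[duplicated(nm)]),
                                           collapse = ", "), call. = FALSE)
  }
  structure(rules, class = "sh_rules")
}

.parse_rule_line <- function(line) {
  colon <- regexpr(" : ", line, fixed = TRUE)
  if (colon < 0L) stop("malformed rule line (no ' : '): ", line, call. = FALSE)
  lhs <- strsplit(trimws(substr(line, 1L, colon - 1L)), "\\s+")[[1L]]
  if (length(lhs) != 3L) {
    stop("malformed rule header (need name priority action): ", line,
         call. = FALSE)
  }
  pat_str <- trimws(substr(line, colon + 3L, nchar(line)))
  elems <- strsplit(pat_str, "\\s+")[[1L]]
  if (!length(elems)) stop("empty pattern in rule: ", lhs[1L], call. = FALSE)
  pattern <- lapply(elems, .parse_element)
  list(name = lhs[1L], priority = as.integer(lhs[2L]),
       action = match.arg(lhs[3L], c("mention", "exclude")),
       pattern = pattern)
}

.parse_element <- function(el) {
  quant <- "one"
  if (grepl("\\*$", el)) { quant <- "star"; el <- sub("\\*$", "", el) }
  else if (grepl("\\?$", el)) { quant <- "opt"; el <- sub("\\?$", "", el) }
  if (startsWith(el, "re=")) {
    # a regex condition takes the whole element ("|" belongs to the regex)
    return(list(quant = quant,
                alts = list(list(list(key = "re", values = substring(el, 4L))))))
  }
  alts <- lapply(strsplit(el, "|", fixed = TRUE)[[1L]], function(alt) {
    conds <- lapply(strsplit(alt, "&", fixed = TRUE)[[1L]], function(c0) {
      kv <- strsplit(c0, "=", fixed = TRUE)[[1L]]
      if (length(kv) < 2L) stop("malformed condition: ", c0, call. = FALSE)
      key <- kv[1L]
      val <- paste(kv[-1L], collapse = "=")
      if (!key %in% c("surface", "lemma", "pos", "sem", "re")) {
        stop("unknown condition key: ", key, call. = FALSE)
      }
      list(key = key,
           values = if (key == "re") val else tolower(strsplit(val, ",", fixed = TRUE)[[1L]]))
    })
    conds
  })
  list(quant = quant, alts = alts)
}

# Does token i of doc satisfy one alternative's conditions?
.token_matches <- function(doc, i, alt) {
  surf <- tolower(doc$tokens$surface[i])
  lem <- tolower(doc$tokens$lemma[i])
  pos <- tolower(doc$tokens$pos[i])
  for (cond in alt) {
    ok <- switch(cond$key,
      surface = surf %in% cond$values,
      lemma = lem %in% cond$values,
      pos = pos %in% cond$values,
      sem = any(tolower(.token_categories(doc, i)) %in% cond$values),
      re = grepl(cond$values, doc$tokens$surface[i], perl = TRUE))
    if (!ok) return(FALSE)
  }
  TRUE
}

.element_matches <- function(doc, i, elem) {
  any(vapply(elem$alts, function(alt) .token_matches(doc, i, alt), TRUE))
}

# Backtracking match of a pattern starting at token i; returns the end
# token id of the longest match, or NA.
.match_pattern_at <- function(doc, i, pattern) {
  n <- nrow(doc$tokens)
  best <- NA_integer_
  rec <- function(ti, pi) {
    if (pi > length(pattern)) {
      end <- ti - 1L
      if (is.na(best) || end > best) best <<- end
      return(invisible(NULL))
    }
    elem <- pattern[[pi]]
    reps <- switch(elem$quant, one = 1L:1L, opt = 1L:0L, star = 3L:0L)
    for (r in reps) {  # greedy: longest repetition first
      if (r == 0L) { rec(ti, pi + 1L); next }
      if (ti + r - 1L > n) next
      ok <- all(vapply(ti:(ti + r - 1L), function(t) .element_matches(doc, t, elem), TRUE))
      if (ok) rec(ti + r, pi + 1L)
    }
    invisible(NULL)
  }
  rec(i, 1L)
  best
}

# All matches of a rule over the document: data.frame(start, end).
.rule_matches <- function(doc, rule) {
  n <- nrow(doc$tokens)
  out <- list()
  for (i in seq_len(n)) {
    e <- .match_pattern_at(doc, i, rule$pattern)
    if (!is.na(e) && e >= i) out[[length(out) + 1L]] <- c(i, e)
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])
}

# Extend a token span to cover any semantic tag it partially overlaps, so
# multi-word lexicon terms are annotated whole.
.extend_to_tags <- function(doc, start, end) {
  t <- doc$tags
  repeat {
    ov <- t$start <= end & t$end >= start
    a <- min(c(start, t$start[ov])); b <- max(c(end, t$end[ov]))
    if (a == start && b == end) break
    start <- a; end <- b
  }
  c(start, end)
}

#' Detect self-harm mentions
#'
#' Applies the inclusion ("mention") rules of the rule set to a tagged
#' document.  Overlapping matches are resolved by longest span, then
#' highest rule priority, then leftmost position.  Mentions receive the
#' default attributes (relevant, current, positive), which layers 4 and 5
#' may later revise.
#'
#' @param doc Tagged \code{sh_document}.
#' @param rules An \code{sh_rules} rule set.
#' @return Document with its \code{mentions} data.frame populated.
#' @export
detect_mentions <- function(doc, rules = load_rules()) {
  stopifnot(inherits(doc, "sh_document"))
  cand <- list()
  for (rule in rules) {
    if (rule$action != "mention") next
    m <- .rule_matches(doc, rule)
    for (r in seq_len(nrow(m))) {
      sp <- .extend_to_tags(doc, m$start[r], m$end[r])
      cand[[length(cand) + 1L]] <-
        list(start = sp[1L], end = sp[2L], priority = rule$priority,
             rule = rule$name)
    }
  }
  if (!length(cand)) {
    doc$mentions <- empty_mentions()
    return(doc)
  }
  df <- do.call(rbind, lapply(cand, as.data.frame, stringsAsFactors = FALSE))
  df <- unique(df)
  # longest span, then priority, then leftmost
  df <- df[order(-(df$end - df$start), -df$priority, df$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) {
      for (j in (i + 1L):nrow(df)) {
        if (keep[j] && df$start[j] <= df$end[i] && df$end[j] >= df$start[i]) {
          keep[j] <- FALSE
        }
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  doc$mentions <- data.frame(
    start = df$start, end = df$end,
    char_start = doc$tokens$char_start[df$start],
    char_end = doc$tokens$char_end[df$end],
    status = "relevant", temporality = "current", polarity = "positive",
    rule = df$rule, priority = df$priority, stringsAsFactors = FALSE)
  doc
}

#' Apply exclusion rules
#'
#' Removes mentions that overlap a match of an "exclude" rule, unless the
#' mention was created by an inclusion rule of higher priority than the
#' exclusion.  Shipped exclusions cover the dosage reading of "OD"
#' (\dQuote{Sertraline 50mg OD AM}) and idiomatic "jump" complements
#' (\dQuote{jump to conclusions}).
#'
#' @param doc Document with mentions.
#' @param rules Rule set containing the exclusion rules.
#' @return Document with excluded mentions removed.
#' @export
apply_exclusions <- function(doc, rules = load_rules()) {
  stopifnot(inherits(doc, "sh_document"))
  if (!nrow(doc$mentions)) return(doc)
  drop <- rep(FALSE, nrow(doc$mentions))
  for (rule in rules) {
    if (rule$action != "exclude") next
    m <- .rule_matches(doc, rule)
    for (r in seq_len(nrow(m))) {
      ov <- doc$mentions$start <= m$end[r] & doc$mentions$end >= m$start[r]
      ov <- ov & doc$mentions$priority < rule$priority
      drop <- drop | ov
    }
  }
  doc$mentions <- doc$mentions[!drop, , drop = FALSE]
  rownames(doc$mentions) <- NULL
  doc
}

# ---- history sections --------------------------------------------------

#' Read the section-header lists
#'
#' @param path Header file with \code{[history]} and \code{[other]}
#'   groups, one header phrase per line.
#' @return List with elements \code{history} and \code{other}.
#' @export
read_history_headers <- function(path = system.file("extdata", "history_headers.txt",
                                                    package = "perisharm")) {
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  grp <- NA_character_
  out <- list(history = character(0), other = character(0))
  for (line in x) {
    if (grepl("^\\[.*\\]$", line)) {
      grp <- sub("^\\[(.*)\\]$", "\\1", line)
    } else if (!is.na(grp) && grp %in% names(out)) {
      out[[grp]] <- c(out[[grp]], tolower(line))
    }
  }
  out
}

# Locate all header occurrences: a header phrase at sentence/line start
# followed by ":".  Returns data.frame(start, end, history) in token ids,
# where end includes the colon.  Longest header wins at a position.
.find_headers <- function(doc, headers) {
  tk <- doc$tokens
  n <- nrow(tk)
  surf <- tolower(tk$surface)
  all_h <- c(headers$history, headers$other)
  is_hist <- c(rep(TRUE, length(headers$history)),
               rep(FALSE, length(headers$other)))
  words <- lapply(all_h, function(h) strsplit(h, "\\s+")[[1L]])
  ord <- order(-vapply(words, length, 1L))
  # headers start at a sentence boundary or right after a previous
  # header's colon (clinical notes often chain headers on one line)
  starts <- which(!duplicated(tk$sentence_id))
  after_colon <- which(surf == ":") + 1L
  starts <- sort(unique(c(starts, after_colon[after_colon <= n])))
  out <- list()
  for (i in starts) {
    for (k in ord) {
      w <- words[[k]]
      len <- length(w)
      if (i + len > n) next
      if (all(surf[i:(i + len - 1L)] == w) && surf[i + len] == ":") {
        out[[length(out) + 1L]] <- c(i, i + len, is_hist[k])
        break
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0), history = logical(0)))
  }
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L], history = as.logical(m[, 3L]))
}

#' Detect history sections
#'
#' A history section opens after a recognised history header (e.g.
#' \dQuote{Past psychiatric history:}) and closes at the next recognised
#' header of either kind or at the end of the document.  Mentions inside a
#' history section are later marked historical.
#'
#' @param doc An \code{sh_document}.
#' @param headers Header lists from \code{\link{read_history_headers}}.
#' @return data.frame with columns \code{start}, \code{end}: token spans
#'   of the section bodies (possibly empty spans are dropped).
#' @export
detect_history_sections <- function(doc, headers = read_history_headers()) {
  stopifnot(inherits(doc, "sh_document"))
  n <- nrow(doc$tokens)
  hd <- .find_headers(doc, headers)
  if (!nrow(hd) || !any(hd$history)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  out <- list()
  for (r in which(hd$history)) {
    body_start <- hd$end[r] + 1L
    nxt <- hd$start[hd$start > hd$end[r]]
    body_end <- if (length(nxt)) min(nxt) - 1L else n
    if (body_start <= body_end) {
      out[[length(out) + 1L]] <- c(body_start, body_end)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])
}
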