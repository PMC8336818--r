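# Document model and linguistic preprocessing (layer 1).
#
# The preprocessor is a deterministic rule-based parser for short clinical
# prose: a regex tokeniser with a configurable exception list (so that
# hyphenated self-harm terms and clinical shorthand such as "self-harm" or
# "fh/o" stay single tokens), closed-class and suffix part-of-speech
# heuristics, a small lemmatiser, and a shallow dependency annotator that
# produces the relations the downstream rules consume (nsubj, dobj, neg,
# aux, prep, pobj, xcomp, amod, det, compound).  It is not a general
# statistical parser; it is scoped to the telegraphic register of
# psychiatric progress notes.

# ---- closed-class word lists -------------------------------------------

.subj_words <- c("she", "he", "they", "i", "we", "it", "who", "patient",
                 "pt", "client", "user", "woman", "lady", "mother",
                 "father", "sister", "brother", "partner", "husband")

.pron_words <- c("she", "her", "he", "him", "his", "hers", "they", "them",
                 "theirs", "i", "me", "we", "us", "you", "it", "who",
                 "herself", "himself", "themselves", "myself", "yourself",
                 "itself", "oneself", "self")

.poss_words <- c("her", "his", "their", "my", "your", "our", "its")

.det_words <- c("the", "a", "an", "this", "these", "those", "no", "any",
                "some", "each", "every", "another", "such")

.aux_words <- c("am", "is", "are", "was", "were", "be", "been", "being",
                "has", "have", "had", "having", "do", "does", "did",
                "will", "shall")

.modal_words <- c("would", "could", "can", "may", "might", "must", "should")

.adp_words <- c("of", "in", "on", "at", "by", "with", "from", "off",
                "through", "down", "up", "out", "over", "into", "onto",
                "under", "after", "during", "against", "around", "near",
                "within", "towards", "toward", "about", "for")

.cconj_words <- c("and", "or", "but", "nor")

.sconj_words <- c("because", "although", "while", "if", "when", "since",
                  "that", "whether", "as")

.neg_part_words <- c("not", "never", "n't")

.num_words <- c("one", "two", "three", "four", "five", "six", "seven",
                "eight", "nine", "ten", "eleven", "twelve", "twenty")

.adv_words <- c("again", "often", "sometimes", "usually", "ever", "still",
                "just", "very", "too", "then", "however", "also", "there",
                "ago", "yesterday", "today", "tonight", "now", "recently",
                "currently", "previously", "historically", "formerly")

.adj_words <- c("current", "chronic", "recent", "previous", "past", "acute",
                "ongoing", "longstanding", "long-standing", "historical",
                "left", "right", "deliberate", "pleasant", "settled",
                "possible", "prone", "young", "old", "former", "suicidal",
                "adequate", "severe", "superficial")

# Base verb forms recognised by the suffix morphology.
.verb_base <- c("be", "have", "do", "take", "cut", "deny", "report", "harm",
                "jump", "climb", "fall", "kill", "die", "try", "attempt",
                "overdose", "lacerate", "burn", "hit", "scratch", "stab",
                "slash", "strangle", "hang", "poison", "ingest", "swallow",
                "drink", "say", "claim", "disclose", "state", "mention",
                "admit", "describe", "tell", "reveal", "think", "start",
                "stop", "tend", "threaten", "want", "wish", "feel", "seem",
                "appear", "go", "come", "make", "get", "give", "use",
                "need", "settle", "present", "note", "discuss", "attend",
                "live", "require", "express", "endorse", "voice", "find",
                "keep", "remain", "continue", "leave", "put", "see", "know",
                "become", "sustain", "end", "inflict", "self-harm", "begin")

# Irregular past / participle forms -> base.
.irregular_verbs <- c(
  took = "take", taken = "take", fell = "fall", fallen = "fall",
  felt = "feel", thought = "think", said = "say", told = "tell",
  drank = "drink", drunk = "drink", went = "go", gone = "go",
  came = "come", made = "make", got = "get", gave = "give",
  knew = "know", known = "know", kept = "keep", left = "leave",
  saw = "see", seen = "see", found = "find", began = "begin",
  begun = "begin", hung = "hang", hanged = "hang", became = "become",
  was = "be", were = "be", is = "be", are = "be", am = "be",
  been = "be", being = "be", did = "do", does = "do", done = "do",
  has = "have", had = "have", having = "have", felt = "feel")

# Semantic priors used only to break noun/verb ties in ambiguous positions
# (sentence-initial telegraphic style: "Denies self-harm" vs "Scratches on
# left arm").
.verb_pref <- c("deny", "report", "say", "claim", "disclose", "state",
                "admit", "describe", "tell", "reveal", "take", "try",
                "threaten", "tend", "think", "appear", "seem", "continue",
                "remain", "require", "endorse")

# Bases restored with a trailing "e" after stripping -ing / -ed.
.e_restore <- c("take", "lacerate", "state", "describe", "reveal",
                "strangle", "overdose", "settle", "use", "require",
                "continue", "voice", "die", "become", "live", "note")

# ---- tokenisation ------------------------------------------------------

#' Read a tokenisation-exception list
#'
#' One term per line, \code{#} comments and blank lines ignored.  Terms are
#' multi-part clinical expressions (e.g. \code{self-harm}, \code{fh/o})
#' that must survive tokenisation as single tokens.
#'
#' @param path Path to the exception file.  Defaults to the list shipped
#'   with the package.
#' @return Character vector of exception terms.
#' @export
read_token_exceptions <- function(path = system.file("extdata", "token_exceptions.txt",
                                                     package = "perisharm")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("tokenisation exception file not found: ", path, call. = FALSE)
  }
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

.escape_regex <- function(x) {
  stringi::stri_replace_all_regex(x, "([\\\\.^$|()\\[\\]{}*+?/-])", "\\\\$1")
}

#' Tokenise clinical text
#'
#' Splits text into word tokens with 0-based half-open character offsets.
#' Terms on the exception list are kept as single tokens whenever they are
#' delimited by whitespace or punctuation.  Contracted negations
#' (\code{didn't}) are split into the stem and \code{n't}.
#'
#' @param text Character scalar (may be empty).
#' @param exceptions Character vector of exception terms.
#' @return data.frame with columns \code{surface}, \code{char_start},
#'   \code{char_end}.
#' @export
tokenize_text <- function(text, exceptions = read_token_exceptions()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE))
  }
  pats <- character(0)
  if (length(exceptions)) {
    exc <- exceptions[order(-nchar(exceptions))]
    pats <- paste0("(?<![A-Za-z0-9])(?:",
                   paste(.escape_regex(exc), collapse = "|"),
                   ")(?![A-Za-z0-9-])")
  }
  pats <- c(pats,
            "[A-Za-z]+n't",                   # contracted negation, split below
            "[A-Za-z]+(?:'[A-Za-z]+)?",       # words, simple clitics
            "[0-9]+(?:\\.[0-9]+)?[A-Za-z]*",  # numbers, doses ("50mg")
            "[^\\s0-9A-Za-z]")                # punctuation / symbols
  pat <- paste0("(?i)(?:", paste(pats, collapse = "|"), ")")
  loc <- stringi::stri_locate_all_regex(text, pat)[[1]]
  if (all(is.na(loc[, 1L]))) {
    return(data.frame(surface = character(0), char_start = integer(0),
                      char_end = integer(0), stringsAsFactors = FALSE))
  }
  surface <- stringi::stri_sub(text, loc[, 1L], loc[, 2L])
  start <- loc[, 1L] - 1L      # 0-based
  end <- loc[, 2L]             # half-open
  # split "didn't" -> "did" + "n't" (keeps the negation particle visible to
  # the dependency annotator)
  contr <- grepl("n't$", surface, ignore.case = TRUE) & nchar(surface) > 3L &
    !tolower(surface) %in% tolower(exceptions)
  if (any(contr)) {
    out_s <- vector("list", length(surface))
    out_a <- vector("list", length(surface))
    out_b <- vector("list", length(surface))
    for (i in seq_along(surface)) {
      if (contr[i]) {
        k <- nchar(surface[i]) - 3L
        out_s[[i]] <- c(substr(surface[i], 1L, k),
                        substr(surface[i], k + 1L, nchar(surface[i])))
        out_a[[i]] <- c(start[i], start[i] + k)
        out_b[[i]] <- c(start[i] + k, end[i])
      } else {
        out_s[[i]] <- surface[i]; out_a[[i]] <- start[i]; out_b[[i]] <- end[i]
      }
    }
    surface <- unlist(out_s); start <- unlist(out_a); end <- unlist(out_b)
  }
  data.frame(surface = surface, char_start = as.integer(start),
             char_end = as.integer(end), stringsAsFactors = FALSE)
}

# ---- lemmatisation -----------------------------------------------------

.lemma_one <- function(w, pos) {
  lw <- tolower(w)
  if (pos %in% c("VERB", "AUX")) {
    if (lw %in% names(.irregular_verbs)) return(unname(.irregular_verbs[[lw]]))
    v <- .strip_verb_suffix(lw)
    if (!is.na(v)) return(v)
    return(lw)
  }
  if (pos %in% c("NOUN", "ADJ")) {
    if (grepl("ies$", lw) && nchar(lw) > 4L) return(sub("ies$", "y", lw))
    # sibilant plurals (glasses, matches, scratches) drop "es"; plain
    # e-stems (overdoses) only drop the "s"
    if (grepl("(ss|x|z|ch|sh)es$", lw)) return(sub("es$", "", lw))
    if (grepl("[a-z]s$", lw) && !grepl("ss$|us$|is$", lw)) return(sub("s$", "", lw))
  }
  lw
}

# Strip -s/-es/-ies/-ing/-ed down to a known verb base; NA if the result is
# not a recognised base.
.strip_verb_suffix <- function(lw) {
  cand <- character(0)
  if (grepl("ies$", lw)) cand <- c(cand, sub("ies$", "y", lw))
  if (grepl("es$", lw))  cand <- c(cand, sub("es$", "", lw), sub("s$", "", lw))
  if (grepl("s$", lw))   cand <- c(cand, sub("s$", "", lw))
  if (grepl("ing$", lw)) {
    stem <- sub("ing$", "", lw)
    cand <- c(cand, stem, paste0(stem, "e"))
    if (grepl("([b-df-hj-np-tv-z])\\1$", stem)) cand <- c(cand, sub(".$", "", stem))
  }
  if (grepl("ied$", lw)) cand <- c(cand, sub("ied$", "y", lw))
  if (grepl("ed$", lw)) {
    stem <- sub("ed$", "", lw)
    cand <- c(cand, stem, paste0(stem, "e"))
    if (grepl("([b-df-hj-np-tv-z])\\1$", stem)) cand <- c(cand, sub(".$", "", stem))
  }
  if (lw %in% .verb_base) return(lw)
  hit <- cand[cand %in% c(.verb_base, .e_restore)]
  if (length(hit)) hit[[1L]] else NA_character_
}

# TRUE when the word is morphologically a form of a known verb base.
.is_verb_form <- function(lw) {
  lw %in% .verb_base || lw %in% names(.irregular_verbs) ||
    !is.na(.strip_verb_suffix(lw))
}

# ---- part-of-speech tagging --------------------------------------------

.pos_tag <- function(surface, gap_newline) {
  n <- length(surface)
  low <- tolower(surface)
  pos <- rep(NA_character_, n)
  is_word <- grepl("^[A-Za-z]", surface)
  nxt_low <- c(low[-1L], "")
  for (i in seq_len(n)) {
    w <- low[i]
    if (!is_word[i]) {
      pos[i] <- if (grepl("^[0-9]", surface[i])) "NUM" else "PUNCT"
      next
    }
    if (surface[i] %in% c("AM", "PM")) { pos[i] <- "NOUN"; next }  # dosing times
    if (w %in% .neg_part_words) { pos[i] <- "PART"; next }
    if (w %in% .poss_words && i < n &&
        (nxt_low[i] %in% .adj_words || !nxt_low[i] %in%
           c(.pron_words, .det_words, .aux_words, .modal_words, .adp_words,
             .cconj_words, .sconj_words, .neg_part_words))) {
      # possessive determiner: "her mother", "her left wrist"
      if (is_word[i + 1L]) { pos[i] <- "DET"; next }
    }
    if (w %in% .pron_words) { pos[i] <- "PRON"; next }
    if (w == "that" && i < n &&
        (nxt_low[i] %in% .adj_words || nxt_low[i] %in% .num_words)) { pos[i] <- "DET"; next }
    if (w %in% .det_words) { pos[i] <- "DET"; next }
    if (w %in% .aux_words) { pos[i] <- "AUX"; next }
    if (w %in% .modal_words) { pos[i] <- "AUX"; next }
    if (w == "to") {
      pos[i] <- if (i < n && (nxt_low[i] %in% .verb_base ||
                              nxt_low[i] %in% names(.irregular_verbs))) "PART" else "ADP"
      next
    }
    if (w %in% .adp_words) { pos[i] <- "ADP"; next }
    if (w %in% .cconj_words) { pos[i] <- "CCONJ"; next }
    if (w %in% .sconj_words) { pos[i] <- "SCONJ"; next }
    if (w %in% .num_words) { pos[i] <- "NUM"; next }
    if (w %in% .adv_words) { pos[i] <- "ADV"; next }
    if (w %in% .adj_words) { pos[i] <- "ADJ"; next }
    if (grepl("ly$", w) && nchar(w) > 3L) { pos[i] <- "ADV"; next }
  }
  # open-class pass: noun/verb disambiguation
  for (i in seq_len(n)) {
    if (!is.na(pos[i])) next
    w <- low[i]
    if (!.is_verb_form(w)) { pos[i] <- "NOUN"; next }
    # previous informative tag (skip particles/adverbs)
    j <- i - 1L
    while (j >= 1L && (is.na(pos[j]) || pos[j] %in% c("ADV"))) j <- j - 1L
    # stop looking back across a sentence/line boundary
    if (j >= 1L && gap_newline[i]) j <- 0L
    prev <- if (j >= 1L) pos[j] else ""
    prev_w <- if (j >= 1L) low[j] else ""
    irregular_past <- w %in% names(.irregular_verbs) && !w %in% .aux_words
    base <- .lemma_one(w, "VERB")
    pos[i] <-
      if (prev %in% c("DET", "ADJ", "NUM")) "NOUN"
      else if (prev == "ADP") { if (grepl("ing$", w)) "VERB" else "NOUN" }
      else if (prev == "AUX" && grepl("[^s]s$", w)) "NOUN"
      else if (prev %in% c("AUX", "PART")) "VERB"
      else if (prev == "PRON" && prev_w %in% .subj_words) "VERB"
      else if (prev == "NOUN" && prev_w %in% .subj_words) "VERB"
      else if (irregular_past) "VERB"
      else if (grepl("ed$", w) || grepl("ing$", w)) "VERB"
      else if (prev %in% c("", "PUNCT", "CCONJ") && grepl("s$", w) &&
                 base %in% .verb_pref) "VERB"
      else "NOUN"
  }
  # -ing noun directly modifying a following noun is adjectival
  # ("self-harming impulse")
  for (i in seq_len(n - 1L)) {
    if (pos[i] %in% c("NOUN", "VERB") && grepl("ing$", low[i]) &&
        pos[i + 1L] == "NOUN") {
      pos[i] <- "ADJ"
    }
  }
  pos
}

# ---- shallow dependency annotation -------------------------------------

# Per-sentence heuristic dependency pass.  Returns list(head, dep) with
# 1-based indices local to the sentence; the root points to itself.
.parse_sentence <- function(surface, pos) {
  n <- length(surface)
  low <- tolower(surface)
  head <- rep(NA_integer_, n)
  dep <- rep("dep", n)
  if (n == 0L) return(list(head = head, dep = dep))

  # 1. verbal groups: AUX*/PART/ADV run ending in a VERB (or a bare AUX)
  pred <- integer(0)
  i <- 1L
  while (i <= n) {
    if (pos[i] %in% c("AUX", "VERB")) {
      j <- i
      # extend over auxiliaries/particles/adverbs up to the first main verb
      while (j < n && pos[j] != "VERB" &&
             pos[j + 1L] %in% c("AUX", "PART", "ADV", "VERB")) j <- j + 1L
      # group head: last VERB in run, else last AUX
      verbs_in <- which(pos[i:j] == "VERB") + i - 1L
      h <- if (length(verbs_in)) verbs_in[length(verbs_in)] else j
      for (k in i:j) {
        if (k == h) next
        head[k] <- h
        dep[k] <- if (low[k] %in% .neg_part_words) "neg"
                  else if (pos[k] %in% c("AUX")) "aux"
                  else if (low[k] == "to") "mark"
                  else if (pos[k] == "VERB") "xcomp"
                  else "advmod"
        if (pos[k] == "VERB" && k < h) { dep[k] <- "aux" }
      }
      pred <- c(pred, h)
      i <- j + 1L
    } else i <- i + 1L
  }

  # 2. link predicates: first is the root; later ones attach leftward
  root <- if (length(pred)) pred[1L] else NA_integer_
  if (length(pred)) {
    head[root] <- root; dep[root] <- "ROOT"
    if (length(pred) > 1L) {
      for (k in 2L:length(pred)) {
        p <- pred[k]
        head[p] <- pred[k - 1L]
        before <- if (p > 1L) low[seq_len(p - 1L)] else character(0)
        prevtok <- if (p > 1L) p - 1L else 0L
        dep[p] <-
          if (prevtok >= 1L && (low[prevtok] == "to" ||
                                (dep[prevtok] %in% c("mark", "aux") && head[prevtok] == p))) "xcomp"
          else if (prevtok >= 1L && pos[prevtok] == "CCONJ") "conj"
          else if (prevtok >= 1L && pos[prevtok] == "SCONJ") "ccomp"
          else if (grepl("ing$", low[p])) "xcomp"
          else "ccomp"
      }
    }
  }

  # 3. noun-phrase chunks
  in_np <- pos %in% c("DET", "NUM", "ADJ", "NOUN", "PRON") & is.na(head)
  np <- list()
  i <- 1L
  while (i <= n) {
    if (in_np[i]) {
      j <- i
      while (j < n && in_np[j + 1L] &&
             pos[j] != "PRON" &&
             !(pos[j] %in% c("NOUN") && pos[j + 1L] %in% c("DET", "NUM"))) {
        j <- j + 1L
      }
      np[[length(np) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  np_head <- integer(length(np))
  for (k in seq_along(np)) {
    a <- np[[k]][1L]; b <- np[[k]][2L]
    nouns <- which(pos[a:b] %in% c("NOUN", "PRON")) + a - 1L
    h <- if (length(nouns)) nouns[length(nouns)] else b
    np_head[k] <- h
    for (t in a:b) {
      if (t == h) next
      head[t] <- h
      dep[t] <- if (low[t] %in% c("no", "neither")) "neg"
                else if (pos[t] == "DET") "det"
                else if (pos[t] == "NUM") "nummod"
                else if (pos[t] == "ADJ") "amod"
                else if (pos[t] == "NOUN") "compound"
                else "dep"
    }
  }

  # 4. attach NP heads and adpositions
  pred_sorted <- sort(pred)
  nearest_left <- function(i, set) {
    s <- set[set < i]
    if (length(s)) max(s) else NA_integer_
  }
  nearest_right <- function(i, set) {
    s <- set[set > i]
    if (length(s)) min(s) else NA_integer_
  }
  group_start <- function(p) {
    # first token of the verbal group headed by p
    g <- which(head == p & dep %in% c("aux", "neg", "mark", "advmod"))
    if (length(g)) min(c(g, p)) else p
  }
  has_dobj <- setNames(rep(FALSE, length(pred)), pred)
  for (k in seq_along(np)) {
    a <- np[[k]][1L]; b <- np[[k]][2L]; h <- np_head[k]
    prev_tok <- if (a > 1L) a - 1L else 0L
    v_prev <- nearest_left(a, pred_sorted)
    v_next <- nearest_right(b, pred_sorted)
    if (prev_tok >= 1L && pos[prev_tok] == "ADP") {
      head[h] <- prev_tok; dep[h] <- "pobj"
    } else if (!is.na(v_next) && group_start(v_next) - b <= 2L) {
      head[h] <- v_next; dep[h] <- "nsubj"
    } else if (!is.na(v_prev)) {
      head[h] <- v_prev
      dep[h] <- if (!has_dobj[[as.character(v_prev)]]) "dobj" else "attr"
      has_dobj[[as.character(v_prev)]] <- TRUE
    } else if (!is.na(v_next)) {
      head[h] <- v_next; dep[h] <- "nsubj"
    }
  }
  if (is.na(root)) {
    # verbless fragment: root is the first NP head, later NP heads chain on
    if (length(np_head)) {
      root <- np_head[1L]
      head[root] <- root; dep[root] <- "ROOT"
    } else {
      root <- 1L; head[1L] <- 1L; dep[1L] <- "ROOT"
    }
  }
  # adpositions attach to the nearest noun or predicate on the left
  for (t in seq_len(n)) {
    if (pos[t] == "ADP" && is.na(head[t])) {
      cand <- c(nearest_left(t, pred_sorted), nearest_left(t, np_head))
      cand <- cand[!is.na(cand)]
      head[t] <- if (length(cand)) max(cand) else root
      dep[t] <- if (head[t] %in% pred_sorted && t == head[t] + 1L) "prt" else "prep"
    }
  }
  # leftovers
  for (t in seq_len(n)) {
    if (!is.na(head[t])) next
    if (pos[t] == "PUNCT") { head[t] <- root; dep[t] <- "punct" }
    else if (pos[t] == "CCONJ") {
      nx <- nearest_right(t, c(pred_sorted, np_head))
      head[t] <- if (is.na(nx)) root else nx; dep[t] <- "cc"
    } else if (pos[t] == "SCONJ") {
      nx <- nearest_right(t, pred_sorted)
      head[t] <- if (is.na(nx)) root else nx; dep[t] <- "mark"
    } else if (low[t] == "to" && pos[t] == "PART") {
      nx <- nearest_right(t, pred_sorted)
      head[t] <- if (is.na(nx)) root else nx; dep[t] <- "mark"
    } else if (low[t] %in% .neg_part_words) {
      nx <- nearest_right(t, c(pred_sorted, np_head))
      head[t] <- if (is.na(nx)) root else nx; dep[t] <- "neg"
    } else if (pos[t] == "ADV") {
      nl <- nearest_left(t, pred_sorted)
      head[t] <- if (is.na(nl)) root else nl; dep[t] <- "advmod"
    } else {
      head[t] <- root
    }
  }
  # guarantee a tree: break any cycle by reattaching to the root
  for (t in seq_len(n)) {
    seen <- logical(n); cur <- t
    repeat {
      if (cur == root || dep[cur] == "ROOT") break
      if (seen[cur]) { head[t] <- root; dep[t] <- "dep"; break }
      seen[cur] <- TRUE
      cur <- head[cur]
    }
  }
  list(head = head, dep = dep)
}

# ---- public API --------------------------------------------------------

#' Construct an annotated document
#' @keywords internal
new_sh_document <- function(doc_id, user_id, text, tokens,
                            tags = NULL, mentions = NULL) {
  if (is.null(tags)) {
    tags <- data.frame(start = integer(0), end = integer(0),
                       category = character(0), stringsAsFactors = FALSE)
  }
  if (is.null(mentions)) mentions <- empty_mentions()
  structure(list(doc_id = doc_id, user_id = user_id, text = text,
                 tokens = tokens, tags = tags, mentions = mentions),
            class = "sh_document")
}

empty_mentions <- function() {
  data.frame(start = integer(0), end = integer(0),
             char_start = integer(0), char_end = integer(0),
             status = character(0), temporality = character(0),
             polarity = character(0), rule = character(0),
             stringsAsFactors = FALSE)
}

#' Linguistic preprocessing of a clinical note
#'
#' Applies sentence detection, tokenisation (with the clinical exception
#' list), part-of-speech tagging, lemmatisation and shallow dependency
#' annotation, returning an annotated document ready for lexical tagging.
#'
#' Character offsets are 0-based and half-open throughout.  Token rows are
#' 1-based (\code{token_id}); \code{head_id} references \code{token_id} and
#' equals the token's own id at the sentence root.
#'
#' @param text Plain UTF-8 note text; may be empty.
#' @param user_id,doc_id Identifiers carried through the pipeline.
#' @param exceptions Tokenisation exception terms.
#' @return An object of class \code{sh_document}.
#' @examples
#' doc <- preprocess("She has a history of self-harm.", "u1", "d1")
#' doc$tokens$surface
#' @export
preprocess <- function(text, user_id = "u", doc_id = "d",
                       exceptions = read_token_exceptions()) {
  tk <- tokenize_text(text, exceptions)
  n <- nrow(tk)
  if (n == 0L) {
    tokens <- data.frame(token_id = integer(0), surface = character(0),
                         lemma = character(0), pos = character(0),
                         head_id = integer(0), dep = character(0),
                         sentence_id = integer(0), char_start = integer(0),
                         char_end = integer(0), stringsAsFactors = FALSE)
    return(new_sh_document(doc_id, user_id, text, tokens))
  }
  # does the gap before token i contain a newline?
  gap_newline <- logical(n)
  if (n > 1L) {
    for (i in 2L:n) {
      gap <- substr(text, tk$char_end[i - 1L] + 1L, tk$char_start[i])
      gap_newline[i] <- grepl("\n", gap, fixed = TRUE)
    }
  }
  pos <- .pos_tag(tk$surface, gap_newline)
  # sentence segmentation: break after ./!/? or before a newline gap
  sent <- integer(n)
  s <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && (tk$surface[i - 1L] %in% c(".", "!", "?") || gap_newline[i])) {
      s <- s + 1L
    }
    sent[i] <- s
  }
  lemma <- vapply(seq_len(n), function(i) .lemma_one(tk$surface[i], pos[i]), "")
  head_id <- integer(n); dep <- character(n)
  for (sid in unique(sent)) {
    idx <- which(sent == sid)
    pr <- .parse_sentence(tk$surface[idx], pos[idx])
    head_id[idx] <- idx[pr$head]
    dep[idx] <- pr$dep
  }
  tokens <- data.frame(token_id = seq_len(n), surface = tk$surface,
                       lemma = lemma, pos = pos, head_id = head_id,
                       dep = dep, sentence_id = sent,
                       char_start = tk$char_start, char_end = tk$char_end,
                       stringsAsFactors = FALSE)
  new_sh_document(doc_id, user_id, text, tokens)
}

#' Context window around a token span
#'
#' Returns the ids of up to \code{width} tokens on each side of the span,
#' truncated at document boundaries and, optionally, at sentence
#' boundaries.  The span's own tokens are never part of the window.
#'
#' @param doc An \code{sh_document}.
#' @param span Integer vector \code{c(start, end)} of 1-based token ids.
#' @param width Non-negative window half-width in tokens (default 10).
#' @param sentence_bounded Truncate the window at the span's sentence
#'   boundaries (default \code{FALSE}: a pure token window).
#' @return Integer vector of token ids.
#' @export
token_window <- function(doc, span, width = 10L, sentence_bounded = FALSE) {
  n <- nrow(doc$tokens)
  a <- span[1L]; b <- span[length(span)]
  if (a < 1L || b > n || a > b) stop("span out of bounds", call. = FALSE)
  if (width <= 0L) return(integer(0))
  left <- if (a > 1L) seq.int(max(1L, a - width), a - 1L) else integer(0)
  right <- if (b < n) seq.int(b + 1L, min(n, b + width)) else integer(0)
  ids <- c(left, right)
  if (sentence_bounded && length(ids)) {
    sids <- unique(doc$tokens$sentence_id[a:b])
    ids <- ids[doc$tokens$sentence_id[ids] %in% sids]
  }
  ids
}

#' @export
print.sh_document <- function(x, ...) {
  cat(sprintf("<sh_document %s (user %s): %d tokens, %d tags, %d mentions>\n",
              x$doc_id, x$user_id, nrow(x$tokens), nrow(x$tags),
              nrow(x$mentions)))
  invisible(x)
}
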