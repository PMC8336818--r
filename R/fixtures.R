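# Synthetic pseudo-EHR fixtures: a frozen bank of worked example
# sentences (the primary regression surface) and a seeded generator of
# short psychiatric progress notes with gold annotations, so every
# pipeline stage and the evaluator are testable without clinical data.

#' Worked-example sentence bank
#'
#' The frozen list of example constructions the rule set is built to
#' handle: span constructions (indicative noun, adjective + noun, verb +
#' object, hazard verb + complement), the four negation conditions,
#' status and temporality cues, and the error-analysis traps (dosage
#' \dQuote{OD}, idiomatic \dQuote{jump}).  \code{mention} is the expected
#' mention substring, or \code{NA} when the sentence must yield no
#' mention.
#'
#' @return data.frame with columns \code{sentence}, \code{mention},
#'   \code{status}, \code{temporality}, \code{polarity}.
#' @export
worked_example_bank <- function() {
  e <- function(sentence, mention, status = "relevant",
                temporality = "current", polarity = "positive") {
    data.frame(sentence = sentence, mention = mention, status = status,
               temporality = temporality, polarity = polarity,
               stringsAsFactors = FALSE)
  }
  none <- function(sentence) e(sentence, NA_character_, NA_character_,
                               NA_character_, NA_character_)
  do.call(rbind, list(
    # span constructions
    e("she had scratches on her arm", "scratches"),
    e("she had a self-harming impulse", "self-harming impulse"),
    e("she cut herself", "cut herself"),
    e("she climbed out a window and fell off", "fell off"),
    e("She lacerated her arm", "lacerated her arm"),
    e("She had cut her left wrist", "cut her left wrist"),
    e("She took an overdose", "overdose"),
    e("She cut herself deliberately", "cut herself"),
    # negation conditions
    e("she did not cut herself", "cut herself", polarity = "negative"),
    e("she did not report harming herself", "harming herself",
      polarity = "negative"),
    e("she denies any self-harm", "self-harm", polarity = "negative"),
    e("Denies self-harm", "self-harm", polarity = "negative"),
    e("Suicide attempts: X", "Suicide attempts", polarity = "negative"),
    e("no history of suicide", "suicide", temporality = "historical",
      polarity = "negative"),
    e("no current or past suicide attempts", "suicide attempts",
      temporality = "historical", polarity = "negative"),
    # status cues
    e("Her mother took an overdose", "overdose", status = "non-relevant"),
    e("thoughts of cutting herself", "cutting herself",
      status = "non-relevant"),
    e("She disclosed having thoughts of cutting herself",
      "cutting herself", status = "non-relevant"),
    e("Possibility of self-harm", "self-harm", status = "non-relevant"),
    e("She would cut herself", "cut herself", status = "non-relevant"),
    e("she thought the self-harm would kill her", "self-harm"),
    # temporality cues
    e("took an overdose ten years ago", "overdose",
      temporality = "historical"),
    e("chronic history of self-harm", "self-harm"),
    e("she started self-harming in her teens", "self-harming",
      temporality = "historical"),
    e("Current episode of self-harm", "self-harm"),
    e("Previous episodes of self-harm", "self-harm",
      temporality = "historical"),
    # error-analysis traps
    none("Sertraline 50mg OD AM"),
    none("She tends to jump to conclusions"),
    none("She jumped down the stairs"),
    e("threatened to jump through a window", "jump through a window"),
    e("2 x OD", "OD")
  ))
}

# ---- note templates ----------------------------------------------------
# Each template is a sentence with an optional embedded gold mention,
# marked by { }.  Attributes are fixed by construction.

.tmpl <- function(text, status = NA, temporality = NA, polarity = NA) {
  list(text = text, status = status, temporality = temporality,
       polarity = polarity)
}

.fixture_templates <- function() {
  list(
    `plain-act` = list(
      .tmpl("She took an {overdose} last night.", "relevant", "current", "positive"),
      .tmpl("She {cut herself} with a razor.", "relevant", "current", "positive"),
      .tmpl("She {cut her left wrist} on Monday.", "relevant", "current", "positive"),
      .tmpl("She {lacerated her arm} yesterday.", "relevant", "current", "positive"),
      .tmpl("She took an {overdose} of paracetamol.", "relevant", "current", "positive")),
    negated = list(
      .tmpl("She denies any {self-harm}.", "relevant", "current", "negative"),
      .tmpl("She did not {cut herself}.", "relevant", "current", "negative"),
      .tmpl("Suicide attempts: X", "relevant", "current", "negative"),
      .tmpl("She did not report {harming herself}.", "relevant", "current", "negative")),
    hedged = list(
      .tmpl("She reported thoughts of {cutting herself}.", "non-relevant", "current", "positive"),
      .tmpl("There is a risk of {self-harm}.", "non-relevant", "current", "positive"),
      .tmpl("Possibility of {self-harm} was discussed.", "non-relevant", "current", "positive"),
      .tmpl("She has a plan to take an {overdose}.", "non-relevant", "current", "positive")),
    historical = list(
      .tmpl("She took an {overdose} ten years ago.", "relevant", "historical", "positive"),
      .tmpl("She started {self-harming} in her teens.", "relevant", "historical", "positive"),
      .tmpl("Previous episodes of {self-harm} were noted.", "relevant", "historical", "positive")),
    `third-party` = list(
      .tmpl("Her mother took an {overdose}.", "non-relevant", "current", "positive"),
      .tmpl("Her sister {cut herself} as well.", "non-relevant", "current", "positive")),
    shorthand = list(
      .tmpl("{DSH} noted on the ward.", "relevant", "current", "positive"),
      .tmpl("2 x {OD} this week.", "relevant", "current", "positive")),
    `exclusion-trap` = list(
      .tmpl("Sertraline 50mg OD AM."),
      .tmpl("Olanzapine 10mg OD nocte."),
      .tmpl("She tends to jump to conclusions."),
      .tmpl("She jumped down the stairs laughing."))
  )
}

.fixture_fillers <- function() {
  c("Seen at home with her care coordinator.",
    "She was settled on the ward.",
    "Dietary intake remains adequate.",
    "She attended the appointment on time.",
    "Sleep has improved this week.",
    "She discussed housing with the social worker.",
    "Mood was described as stable.",
    "She is engaging well with the team.")
}

# The special template "Suicide attempts: X" carries no braces; handle
# brace-less gold templates by locating a fixed substring.
.special_gold <- list(`Suicide attempts: X` = "Suicide attempts")

#' Fixture generation settings
#'
#' Defaults emulate the shape of the reference cohort: roughly one user
#' in five ever documented with a perinatal self-harm act, and affected
#' users usually carrying more than one mention because real events are
#' re-documented at later visits.
#'
#' @param n_users Number of service-users.
#' @param notes_range Range (length-2) of notes per user.
#' @param p_case Probability a user is a self-harm case.
#' @param p_true_mention Probability each of a case's notes carries a
#'   true-mention sentence.
#' @param class_mix Named proportions over non-true phenomenon classes
#'   (negated, hedged, historical, third-party, exclusion-trap).
#' @param seed Random seed.
#' @return List of class \code{sh_fixture_spec}.
#' @export
fixture_spec <- function(n_users = 50L, notes_range = c(1L, 6L),
                         p_case = 0.25, p_true_mention = 0.3,
                         class_mix = c(negated = 0.3, hedged = 0.25,
                                       historical = 0.2,
                                       `third-party` = 0.15,
                                       `exclusion-trap` = 0.1),
                         seed = 7L) {
  stopifnot(n_users >= 1L, length(notes_range) == 2L,
            notes_range[1L] >= 1L, notes_range[2L] >= notes_range[1L],
            p_case >= 0, p_case <= 1, p_true_mention >= 0,
            p_true_mention <= 1, abs(sum(class_mix) - 1) < 1e-8)
  structure(list(n_users = as.integer(n_users),
                 notes_range = as.integer(notes_range),
                 p_case = p_case, p_true_mention = p_true_mention,
                 class_mix = class_mix, seed = as.integer(seed)),
            class = "sh_fixture_spec")
}

# Render one template into (text, gold rows with 0-based offsets).
.render_template <- function(tmpl) {
  txt <- tmpl$text
  m <- regexpr("\\{[^}]*\\}", txt)
  if (m > 0L) {
    inner <- substr(txt, m + 1L, m + attr(m, "match.length") - 2L)
    before <- substr(txt, 1L, m - 1L)
    after <- substr(txt, m + attr(m, "match.length"), nchar(txt))
    text <- paste0(before, inner, after)
    gold <- data.frame(char_start = nchar(before),
                       char_end = nchar(before) + nchar(inner),
                       text = inner, status = tmpl$status,
                       temporality = tmpl$temporality,
                       polarity = tmpl$polarity, stringsAsFactors = FALSE)
  } else if (txt %in% names(.special_gold)) {
    inner <- .special_gold[[txt]]
    at <- regexpr(inner, txt, fixed = TRUE)
    text <- txt
    gold <- data.frame(char_start = at - 1L,
                       char_end = at - 1L + nchar(inner), text = inner,
                       status = tmpl$status, temporality = tmpl$temporality,
                       polarity = tmpl$polarity, stringsAsFactors = FALSE)
  } else {
    text <- txt
    gold <- NULL
  }
  list(text = text, gold = gold)
}

#' Generate a synthetic gold-annotated corpus
#'
#' Deterministic given the seed.  Each note is assembled from neutral
#' filler sentences plus sampled phenomenon templates; gold mention
#' offsets and attributes are emitted by construction, and per-user gold
#' flags are recomputed from the gold mentions.
#'
#' @param spec \code{\link{fixture_spec}} settings.
#' @param k Heuristic threshold used for the gold heuristic flag.
#' @return List of class \code{sh_gold_corpus} with \code{corpus}
#'   (data.frame doc_id, user_id, text), \code{gold_mentions} (mention
#'   table layout) and \code{gold_users} (user_id, n_true_mentions,
#'   flagged_plain, flagged_heuristic).
#' @export
generate_corpus <- function(spec = fixture_spec(), k = 2L) {
  stopifnot(inherits(spec, "sh_fixture_spec"))
  set.seed(spec$seed)
  templates <- .fixture_templates()
  fillers <- .fixture_fillers()
  classes <- names(spec$class_mix)
  corpus <- list(); gold <- list()
  doc_n <- 0L
  for (u in seq_len(spec$n_users)) {
    user_id <- sprintf("U%03d", u)
    is_case <- stats::runif(1) < spec$p_case
    n_notes <- sample(seq.int(spec$notes_range[1L], spec$notes_range[2L]), 1L)
    for (d in seq_len(n_notes)) {
      doc_n <- doc_n + 1L
      doc_id <- sprintf("D%04d", doc_n)
      phen <- list()
      if (is_case && stats::runif(1) < spec$p_true_mention) {
        cls <- sample(c("plain-act", "shorthand"), 1L, prob = c(0.8, 0.2))
        t <- templates[[cls]][[sample(length(templates[[cls]]), 1L)]]
        phen[[length(phen) + 1L]] <- .render_template(t)
      }
      # 0-2 non-true phenomenon sentences
      for (j in seq_len(sample(0:2, 1L))) {
        cls <- sample(classes, 1L, prob = spec$class_mix)
        t <- templates[[cls]][[sample(length(templates[[cls]]), 1L)]]
        phen[[length(phen) + 1L]] <- .render_template(t)
      }
      # interleave phenomenon sentences with two fillers each, so one
      # sentence's cue words stay outside its neighbours' token windows
      sents <- list(list(text = sample(fillers, 1L), gold = NULL))
      for (p in phen) {
        sents[[length(sents) + 1L]] <- p
        for (f in sample(fillers, 2L)) {
          sents[[length(sents) + 1L]] <- list(text = f, gold = NULL)
        }
      }
      # assemble with single-space joins, tracking offsets
      text <- ""; rows <- list()
      for (s in sents) {
        off <- nchar(text) + if (nzchar(text)) 1L else 0L
        text <- if (nzchar(text)) paste(text, s$text) else s$text
        if (!is.null(s$gold)) {
          g <- s$gold
          g$char_start <- g$char_start + off
          g$char_end <- g$char_end + off
          g$doc_id <- doc_id; g$user_id <- user_id
          rows[[length(rows) + 1L]] <- g
        }
      }
      corpus[[doc_n]] <- data.frame(doc_id = doc_id, user_id = user_id,
                                    text = text, stringsAsFactors = FALSE)
      if (length(rows)) gold[[length(gold) + 1L]] <- do.call(rbind, rows)
    }
  }
  corpus <- do.call(rbind, corpus)
  gold_mentions <- if (length(gold)) do.call(rbind, gold) else
    data.frame(doc_id = character(0), user_id = character(0),
               char_start = integer(0), char_end = integer(0),
               text = character(0), status = character(0),
               temporality = character(0), polarity = character(0),
               stringsAsFactors = FALSE)
  rownames(gold_mentions) <- NULL
  cols <- c("doc_id", "user_id", "char_start", "char_end", "text",
            "status", "temporality", "polarity")
  gold_mentions <- gold_mentions[, intersect(cols, names(gold_mentions)),
                                 drop = FALSE]
  gold_users <- aggregate_users(gold_mentions,
                                users = unique(corpus$user_id), k = k)
  structure(list(corpus = corpus, gold_mentions = gold_mentions,
                 gold_users = gold_users, spec = spec),
            class = "sh_gold_corpus")
}

#' @export
print.sh_gold_corpus <- function(x, ...) {
  cat(sprintf("<sh_gold_corpus: %d notes, %d users, %d gold mentions, %d flagged users>\n",
              nrow(x$corpus), length(unique(x$corpus$user_id)),
              nrow(x$gold_mentions), sum(x$gold_users$flagged_plain)))
  invisible(x)
}
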