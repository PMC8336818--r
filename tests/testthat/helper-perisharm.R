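# Shared fixtures: pipeline resources are loaded once per test run.

ps_lexicons <- load_lexicons()
ps_rules <- load_rules()
ps_headers <- read_history_headers()
ps_exceptions <- read_token_exceptions()

ps_annotate <- function(text, user_id = "u", doc_id = "d",
                        config = sh_config()) {
  annotate_note(text, user_id = user_id, doc_id = doc_id,
                lexicons = ps_lexicons, rules = ps_rules,
                headers = ps_headers, exceptions = ps_exceptions,
                config = config)
}

ps_mention_texts <- function(doc) {
  m <- doc$mentions
  substr(rep(doc$text, nrow(m)), m$char_start + 1L, m$char_end)
}

# ---- independent metric oracles (explicit pair counting) ---------------

oracle_kappa <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n)) if (a[i] == b[i]) agree <- agree + 1
  po <- agree / n
  pe <- 0
  for (cl in unique(c(a, b))) {
    na <- 0; nb <- 0
    for (i in seq_len(n)) {
      if (a[i] == cl) na <- na + 1
      if (b[i] == cl) nb <- nb + 1
    }
    pe <- pe + (na / n) * (nb / n)
  }
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

oracle_prf <- function(gold, pred) {
  classes <- sort(unique(c(gold, pred)))
  tp <- fp <- fn <- 0
  per_p <- per_r <- per_f <- numeric(0)
  for (cl in classes) {
    ctp <- cfp <- cfn <- 0
    for (i in seq_along(gold)) {
      if (gold[i] == cl && pred[i] == cl) ctp <- ctp + 1
      if (gold[i] != cl && pred[i] == cl) cfp <- cfp + 1
      if (gold[i] == cl && pred[i] != cl) cfn <- cfn + 1
    }
    tp <- tp + ctp; fp <- fp + cfp; fn <- fn + cfn
    if (cl %in% gold) {
      p <- if (ctp + cfp == 0) NA else ctp / (ctp + cfp)
      r <- ctp / (ctp + cfn)
      f <- if (is.na(p)) NA else if (p + r == 0) 0 else 2 * p * r / (p + r)
      per_p <- c(per_p, p); per_r <- c(per_r, r); per_f <- c(per_f, f)
    }
  }
  list(micro = c(p = tp / (tp + fp), r = tp / (tp + fn)),
       macro = c(p = mean(per_p, na.rm = TRUE),
                 r = mean(per_r, na.rm = TRUE),
                 f = mean(per_f, na.rm = TRUE)))
}
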