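# Service-user-level aggregation with the >=2-true-mentions heuristic.

#' Is a mention a "true" mention?
#'
#' A true mention is an asserted, current act: status relevant, polarity
#' positive, temporality current.
#'
#' @param status,temporality,polarity Attribute vectors (recycled).
#' @return Logical vector.
#' @export
is_true_mention <- function(status, temporality, polarity) {
  status == "relevant" & temporality == "current" & polarity == "positive"
}

#' Aggregate mentions to service-user level
#'
#' Pools mention counts over all of each user's documents and flags users
#' two ways: \code{flagged_plain} (at least one true mention) and
#' \code{flagged_heuristic} (at least \code{k} true mentions; the
#' heuristic rests on real self-harm events being re-documented at
#' subsequent visits, so repeat mentions of one event are deliberately not
#' deduplicated).
#'
#' @param mentions Mention table from \code{\link{mention_table}} (or a
#'   gold table with the same columns).
#' @param users Optional character vector of all user ids (so users with
#'   zero mentions appear in the summary).
#' @param k Heuristic threshold (default 2).
#' @param distinct_documents Count at most one true mention per document
#'   towards the heuristic (default \code{FALSE}).
#' @return data.frame with one row per user: \code{user_id},
#'   \code{n_documents}, \code{n_mentions_total}, \code{n_true_mentions},
#'   \code{flagged_plain}, \code{flagged_heuristic}.
#' @export
aggregate_users <- function(mentions, users = NULL, k = 2L,
                            distinct_documents = FALSE) {
  stopifnot(k >= 1L)
  ids <- unique(c(as.character(users), as.character(mentions$user_id)))
  ids <- sort(ids)
  out <- data.frame(user_id = ids, n_documents = 0L, n_mentions_total = 0L,
                    n_true_mentions = 0L, flagged_plain = FALSE,
                    flagged_heuristic = FALSE, stringsAsFactors = FALSE)
  if (nrow(mentions)) {
    tr <- is_true_mention(mentions$status, mentions$temporality,
                          mentions$polarity)
    for (i in seq_along(ids)) {
      sel <- mentions$user_id == ids[i]
      out$n_documents[i] <- length(unique(mentions$doc_id[sel]))
      out$n_mentions_total[i] <- sum(sel)
      out$n_true_mentions[i] <-
        if (distinct_documents) length(unique(mentions$doc_id[sel & tr]))
        else sum(sel & tr)
    }
  }
  out$flagged_plain <- out$n_true_mentions >= 1L
  out$flagged_heuristic <- out$n_true_mentions >= as.integer(k)
  out
}
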