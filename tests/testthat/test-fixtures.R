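# Synthetic corpus generator and the worked-example bank.

test_that("generation is byte-identical under a fixed seed", {
  g1 <- generate_corpus(fixture_spec(n_users = 10L, seed = 33L))
  g2 <- generate_corpus(fixture_spec(n_users = 10L, seed = 33L))
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$gold_mentions, g2$gold_mentions)
  expect_identical(g1$gold_users, g2$gold_users)
  g3 <- generate_corpus(fixture_spec(n_users = 10L, seed = 34L))
  expect_false(identical(g1$corpus$text, g3$corpus$text))
})

test_that("gold offsets point at the gold mention text", {
  g <- generate_corpus(fixture_spec(n_users = 15L, seed = 5L))
  gm <- g$gold_mentions
  expect_gt(nrow(gm), 0L)
  for (i in seq_len(nrow(gm))) {
    txt <- g$corpus$text[g$corpus$doc_id == gm$doc_id[i]]
    expect_identical(substr(txt, gm$char_start[i] + 1L, gm$char_end[i]),
                     gm$text[i])
  }
})

test_that("gold user flags are recomputable from gold mentions", {
  g <- generate_corpus(fixture_spec(n_users = 20L, seed = 9L), k = 2L)
  re <- aggregate_users(g$gold_mentions, users = unique(g$corpus$user_id),
                        k = 2L)
  expect_identical(g$gold_users, re)
  # and satisfy heuristic monotonicity
  expect_true(all(!g$gold_users$flagged_heuristic |
                    g$gold_users$flagged_plain))
})

test_that("an all-negated mix yields no true mentions and no flagged users", {
  spec <- fixture_spec(n_users = 12L, p_case = 0, seed = 21L,
                       class_mix = c(negated = 1, hedged = 0, historical = 0,
                                     `third-party` = 0, `exclusion-trap` = 0))
  g <- generate_corpus(spec)
  if (nrow(g$gold_mentions)) {
    expect_true(all(g$gold_mentions$polarity == "negative"))
  }
  expect_false(any(g$gold_users$flagged_plain))
  # a correct pipeline flags zero users on this corpus
  docs <- annotate_corpus(g$corpus, lexicons = ps_lexicons,
                          rules = ps_rules, headers = ps_headers,
                          exceptions = ps_exceptions)
  pred <- aggregate_users(mention_table(docs),
                          users = unique(g$corpus$user_id))
  expect_false(any(pred$flagged_plain))
})

test_that("generated text uses placeholder identifiers only", {
  g <- generate_corpus(fixture_spec(n_users = 10L, seed = 2L))
  expect_true(all(grepl("^U\\d+$", g$corpus$user_id)))
  expect_true(all(grepl("^D\\d+$", g$corpus$doc_id)))
  # no names beyond generic role words in the templates
  expect_false(any(grepl("\\b(Mr|Mrs|Ms|Dr)\\.?\\s", g$corpus$text)))
})

test_that("the worked-example bank covers the printed constructions", {
  bank <- worked_example_bank()
  expect_gte(nrow(bank), 25L)
  expect_true(any(is.na(bank$mention)))           # must-not-detect traps
  expect_true(all(c("she cut herself", "Sertraline 50mg OD AM") %in%
                    bank$sentence))
  with_m <- bank[!is.na(bank$mention), ]
  expect_true(all(mapply(grepl, with_m$mention, with_m$sentence,
                         MoreArgs = list(fixed = TRUE))))
  expect_true(all(with_m$status %in% c("relevant", "non-relevant")))
  expect_true(all(with_m$temporality %in% c("current", "historical")))
  expect_true(all(with_m$polarity %in% c("positive", "negative")))
})
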