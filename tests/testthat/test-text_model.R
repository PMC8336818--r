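# Layer 1: tokenisation, offsets, windows, shallow parse.

test_that("hyphenated and shorthand terms survive tokenisation as single tokens", {
  doc <- preprocess("She has a history of self-harm.", exceptions = ps_exceptions)
  expect_true("self-harm" %in% doc$tokens$surface)
  expect_false("harm" %in% doc$tokens$surface)

  for (term in c("self-harm", "self-injury", "self-harming", "fh/o", "d/s/h")) {
    d <- preprocess(sprintf("Noted %s on review.", term),
                    exceptions = ps_exceptions)
    expect_true(term %in% d$tokens$surface, label = term)
  }
  # but only when delimited: inside a longer word the exception must not fire
  d <- preprocess("self-harming", exceptions = ps_exceptions)
  expect_identical(d$tokens$surface, "self-harming")
})

test_that("empty text yields an empty document", {
  doc <- preprocess("", "u0", "d0")
  expect_identical(nrow(doc$tokens), 0L)
  expect_identical(length(unique(doc$tokens$sentence_id)), 0L)
  expect_identical(nrow(mention_table(ps_annotate(""))), 0L)
})

test_that("character offsets reconstruct the text exactly", {
  texts <- c("She took an overdose last night.",
             "Past psychiatric history: 2 x OD.\nCurrent presentation: settled.",
             "Sertraline 50mg OD AM & nocte <review>.",
             "Denies d/s/h; fh/o depression.")
  for (txt in texts) {
    doc <- preprocess(txt, exceptions = ps_exceptions)
    tk <- doc$tokens
    expect_true(all(tk$char_start < tk$char_end))
    expect_true(all(diff(tk$char_start) > 0))
    # tokens must not overlap
    expect_true(all(tk$char_end[-nrow(tk)] <= tk$char_start[-1]))
    # substring at each token's offsets is its surface
    expect_identical(substr(rep(txt, nrow(tk)), tk$char_start + 1L, tk$char_end),
                     tk$surface)
    # and everything outside token spans is whitespace
    chars <- strsplit(txt, "")[[1L]]
    covered <- rep(FALSE, length(chars))
    for (i in seq_len(nrow(tk))) {
      covered[(tk$char_start[i] + 1L):tk$char_end[i]] <- TRUE
    }
    expect_true(all(grepl("^\\s$", chars[!covered])))
  }
})

test_that("every token's head chain terminates at a sentence root", {
  txts <- c("She did not cut herself.",
            "Her mother took an overdose and was admitted.",
            "Past psychiatric history: two overdoses. Current presentation: settled.")
  for (txt in txts) {
    doc <- preprocess(txt, exceptions = ps_exceptions)
    tk <- doc$tokens
    for (i in tk$token_id) {
      cur <- i; steps <- 0L
      while (tk$head_id[cur] != cur) {
        expect_identical(tk$sentence_id[tk$head_id[cur]], tk$sentence_id[cur])
        cur <- tk$head_id[cur]
        steps <- steps + 1L
        expect_lt(steps, nrow(tk) + 1L)
      }
    }
  }
})

test_that("negation attaches to its governing verb in the dependency pass", {
  # frozen regression parse for the canonical negation sentence
  doc <- preprocess("She did not cut herself.", exceptions = ps_exceptions)
  tk <- doc$tokens
  neg <- which(tk$dep == "neg")
  expect_length(neg, 1L)
  expect_identical(tk$surface[neg], "not")
  expect_identical(tk$surface[tk$head_id[neg]], "cut")
  expect_identical(tk$surface[which(tk$dep == "dobj")], "herself")
})

test_that("token_window obeys width, boundaries and the sentence switch", {
  doc <- preprocess(paste(rep("word", 5), collapse = " "))
  expect_identical(token_window(doc, c(3L, 3L), 10L), c(1L, 2L, 4L, 5L))
  expect_identical(token_window(doc, c(3L, 3L), 0L), integer(0))
  expect_error(token_window(doc, c(0L, 3L), 2L), "out of bounds")

  doc30 <- preprocess(paste(rep("word", 30), collapse = " "))
  expect_identical(token_window(doc30, c(15L, 16L), 10L),
                   c(5:14, 17:26))
  # property: |window| <= 2*width, and == 2*width away from the edges
  for (a in c(1L, 2L, 11L, 20L, 29L)) {
    w <- token_window(doc30, c(a, a), 10L)
    expect_lte(length(w), 20L)
    expect_false(a %in% w)
    if (a > 10L && a <= 20L) expect_identical(length(w), 20L)
  }
  # sentence-bounded variant stops at sentence breaks
  doc2 <- preprocess("One two three. Four five six. Seven eight nine.")
  mid <- which(doc2$tokens$surface == "five")
  unb <- token_window(doc2, c(mid, mid), 10L)
  bnd <- token_window(doc2, c(mid, mid), 10L, sentence_bounded = TRUE)
  expect_gt(length(unb), length(bnd))
  expect_setequal(doc2$tokens$surface[bnd], c("Four", "six", "."))
})
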