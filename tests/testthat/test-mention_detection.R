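# Layer 3: span grammar, exclusions, history sections.

test_that("span coding rules pick the right extent", {
  cases <- list(
    list("she had scratches on her arm", "scratches"),       # indicative noun
    list("she had a self-harming impulse", "self-harming impulse"),  # adj + noun
    list("she cut herself", "cut herself"),                  # verb + object
    list("she climbed out a window and fell off", "fell off"))  # hazard verb
  for (cs in cases) {
    doc <- ps_annotate(cs[[1L]])
    expect_identical(ps_mention_texts(doc), cs[[2L]], label = cs[[1L]])
  }
})

test_that("no two mentions overlap and identical spans are collapsed", {
  doc <- ps_annotate("Suicide attempts and self-harm were discussed; she cut herself.")
  m <- doc$mentions
  expect_gt(nrow(m), 1L)
  m <- m[order(m$start), ]
  expect_true(all(m$end[-nrow(m)] < m$start[-1]))
  expect_identical(anyDuplicated(m[, c("start", "end")]), 0L)
})

test_that("dosage OD and idiomatic jump are excluded, real uses kept", {
  expect_identical(nrow(ps_annotate("Sertraline 50mg OD AM")$mentions), 0L)
  expect_identical(nrow(ps_annotate("Olanzapine 10mg OD nocte.")$mentions), 0L)
  expect_identical(nrow(ps_annotate("tends to jump to conclusions")$mentions), 0L)
  expect_identical(nrow(ps_annotate("She jumped down the stairs")$mentions), 0L)
  expect_identical(ps_mention_texts(ps_annotate("threatened to jump through a window")),
                   "jump through a window")
  expect_identical(ps_mention_texts(ps_annotate("2 x OD")), "OD")
  # a plain overdose next to a drug name (no dose, no frequency) is real
  expect_identical(ps_mention_texts(ps_annotate("She took an overdose of paracetamol.")),
                   "overdose")
})

test_that("rule files are validated", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("r1 10 mention : sem=SH", "r1 20 exclude : surface=od"), tmp)
  expect_error(load_rules(tmp), "duplicate")
  writeLines("r1 10 mention", tmp)
  expect_error(load_rules(tmp), "malformed")
  writeLines("r1 10 mention : badkey=1", tmp)
  expect_error(load_rules(tmp), "unknown condition key")
})

test_that("history sections span from a history header to the next header", {
  doc <- preprocess("Past psychiatric history: two overdoses. Current presentation: settled.",
                    exceptions = ps_exceptions)
  sec <- detect_history_sections(doc, ps_headers)
  expect_identical(nrow(sec), 1L)
  covered <- doc$tokens$surface[sec$start[1]:sec$end[1]]
  expect_identical(covered, c("two", "overdoses", "."))

  # no headers -> no sections
  doc2 <- preprocess("She was seen at home today.", exceptions = ps_exceptions)
  expect_identical(nrow(detect_history_sections(doc2, ps_headers)), 0L)

  # two consecutive headers: the first body is empty (dropped), the second
  # runs to the end of the document
  doc3 <- preprocess("Past psychiatric history: Forensic history: two arrests",
                     exceptions = ps_exceptions)
  sec3 <- detect_history_sections(doc3, ps_headers)
  expect_identical(nrow(sec3), 1L)
  expect_identical(sec3$end[1], nrow(doc3$tokens))
  expect_identical(doc3$tokens$surface[sec3$start[1]], "two")
})

test_that("rule application is deterministic and order-stable", {
  txt <- paste("Past psychiatric history: two overdoses.",
               "She denies any self-harm. Her mother took an overdose.",
               "2 x OD this week. Sertraline 50mg OD AM.")
  d1 <- ps_annotate(txt)
  d2 <- ps_annotate(txt)
  expect_identical(d1$mentions, d2$mentions)
  expect_true(all(diff(d1$mentions$start) > 0))
})
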