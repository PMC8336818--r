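# Layers 4-5: polarity, status, temporality.

attrs_of <- function(text, config = sh_config()) {
  m <- ps_annotate(text, config = config)$mentions
  expect_identical(nrow(m), 1L, label = text)
  c(status = m$status, temporality = m$temporality, polarity = m$polarity)
}

test_that("the four negation conditions each produce negative polarity", {
  expect_identical(attrs_of("she did not cut herself")[["polarity"]], "negative")      # heads a neg dep
  expect_identical(attrs_of("she did not report harming herself")[["polarity"]], "negative")  # negated R_SPEECH governor
  expect_identical(attrs_of("she denies any self-harm")[["polarity"]], "negative")     # NEGATION governor
  expect_identical(attrs_of("Suicide attempts: X")[["polarity"]], "negative")          # symbol negation
  expect_identical(attrs_of("Self-harm: nil")[["polarity"]], "negative")
  expect_identical(attrs_of("she cut herself")[["polarity"]], "positive")
})

test_that("hedging, modality and third-party cues demote status", {
  expect_identical(attrs_of("thoughts of cutting herself")[["status"]], "non-relevant")
  expect_identical(attrs_of("Possibility of self-harm")[["status"]], "non-relevant")
  expect_identical(attrs_of("her mother took an overdose")[["status"]], "non-relevant")
  expect_identical(attrs_of("There is a risk of self-harm.")[["status"]], "non-relevant")
  expect_identical(attrs_of("she took an overdose last night")[["status"]], "relevant")
  # window width: a family cue 3 tokens left links; far away it must not
  expect_identical(attrs_of("Her mother was informed after she took an overdose.")[["status"]],
                   "relevant")
})

test_that("a trailing modal in a separate predication does not demote (fixed mode)", {
  txt <- "she thought the self-harm would kill her"
  expect_identical(attrs_of(txt)[["status"]], "relevant")
  faithful <- sh_config(paper_faithful_mode = TRUE)
  expect_identical(attrs_of(txt, config = faithful)[["status"]], "non-relevant")
})

test_that("temporality follows past/present cues, life stages and sections", {
  expect_identical(attrs_of("took an overdose ten years ago")[["temporality"]], "historical")
  expect_identical(attrs_of("she started self-harming in her teens")[["temporality"]], "historical")
  expect_identical(attrs_of("chronic history of self-harm")[["temporality"]], "current")
  expect_identical(attrs_of("Current episode of self-harm")[["temporality"]], "current")
  expect_identical(attrs_of("no history of suicide")[["temporality"]], "historical")
  # history section overrides a nearer present cue
  sec_txt <- "Past psychiatric history: two overdoses. Current presentation: settled."
  m <- ps_annotate(sec_txt)$mentions
  expect_identical(m$temporality, "historical")
})

test_that("coordinated current-or-past negation is historical and negative", {
  a <- attrs_of("no current or past suicide attempts")
  expect_identical(a[["temporality"]], "historical")
  expect_identical(a[["polarity"]], "negative")
})

test_that("defaults are relevant, current, positive with no cues", {
  a <- attrs_of("She took an overdose.")
  expect_identical(unname(a), c("relevant", "current", "positive"))
})

test_that("adding a PAST cue in the window only moves current to historical", {
  # monotone cue semantics: pad a past marker to increasing distances from
  # the mention; wherever the padded sentence differs from the cue-free
  # one, the change is current -> historical, never the reverse
  for (pad in 0:12) {
    filler <- paste(rep("and reviewed", pad), collapse = " ")
    plain <- attrs_of(trimws(paste("She took an overdose", filler, ".")))
    cued <- attrs_of(trimws(paste("She took an overdose", filler, "previously .")))
    expect_identical(plain[["temporality"]], "current")
    expect_false(plain[["temporality"]] == "historical" &&
                   cued[["temporality"]] == "current")
  }
  # inside the 10-token window the cue must take effect
  expect_identical(attrs_of("She took an overdose previously.")[["temporality"]],
                   "historical")
})

test_that("attribute resolution reads only earlier layers (order independence)", {
  txt <- "She denies any self-harm and previously took an overdose."
  doc <- ps_annotate(txt)
  sections <- detect_history_sections(doc, ps_headers)
  m <- doc$mentions
  for (r in seq_len(nrow(m))) {
    expect_identical(resolve_polarity(doc, m$start[r], m$end[r]), m$polarity[r])
    expect_identical(resolve_status(doc, m$start[r], m$end[r]), m$status[r])
    expect_identical(resolve_temporality(doc, m$start[r], m$end[r], sections),
                     m$temporality[r])
  }
})
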