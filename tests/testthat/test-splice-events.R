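se_fixture <- function(strand = "+") {
  t1 <- transcript_model("t1", "g", "chr1", strand,
                         cbind(c(0, 200, 400), c(100, 300, 500)))
  t2 <- transcript_model("t2", "g", "chr1", strand,
                         cbind(c(0, 400), c(100, 500)))
  build_annotation(list(t1, t2))
}

test_that("single-transcript genes yield no events", {
  ann <- build_annotation(list(
    transcript_model("t", "g", "chr1", "+",
                     cbind(c(0, 200), c(100, 300)))))
  expect_equal(nrow(enumerate_events(ann)), 0)
  expect_true(all(count_events(enumerate_events(ann))$known == 0))
})

test_that("an internal-exon difference gives exactly one SE", {
  ev <- enumerate_events(se_fixture())
  se <- ev[ev$type == "SE", ]
  expect_equal(nrow(se), 1)
  expect_equal(se$signature, "100-200-300-400")
  expect_equal(se$inclusion, "t1")
  expect_equal(se$exclusion, "t2")
})

test_that("A5/A3 labels swap between strands at fixed coordinates", {
  ev_p <- enumerate_events(se_fixture("+"))
  ev_m <- enumerate_events(se_fixture("-"))
  sig_p <- split(ev_p$signature, ev_p$type)
  sig_m <- split(ev_m$signature, ev_m$type)
  expect_equal(sig_p$A5, sig_m$A3)
  expect_equal(sig_p$A3, sig_m$A5)
  expect_equal(sig_p$SE, sig_m$SE)
})

test_that("RI, MX, AF and AL are detected on hand fixtures", {
  # RI: exon spanning the intron with matching outer boundaries
  r1 <- transcript_model("r1", "g", "chr1", "+",
                         cbind(c(0, 200), c(100, 300)))
  r2 <- transcript_model("r2", "g", "chr1", "+", cbind(0, 300))
  ev <- enumerate_events(build_annotation(list(r1, r2)))
  expect_equal(ev$type, "RI")
  expect_equal(ev$signature, "0-100-200-300")
  expect_equal(ev$inclusion, "r2")

  # MX: two non-overlapping cassettes sharing both flanks
  m1 <- transcript_model("m1", "g", "chr1", "+",
                         cbind(c(0, 200, 600), c(100, 300, 700)))
  m2 <- transcript_model("m2", "g", "chr1", "+",
                         cbind(c(0, 400, 600), c(100, 500, 700)))
  ev <- enumerate_events(build_annotation(list(m1, m2)))
  expect_setequal(ev$type, c("MX", "A5", "A3"))
  expect_equal(ev$signature[ev$type == "MX"],
               "100-200-300-600-100-400-500-600")

  # AF: distinct first exons splicing into one acceptor
  a1 <- transcript_model("a1", "g", "chr1", "+",
                         cbind(c(0, 600), c(100, 700)))
  a2 <- transcript_model("a2", "g", "chr1", "+",
                         cbind(c(300, 600), c(400, 700)))
  ev <- enumerate_events(build_annotation(list(a1, a2)))
  expect_true("AF" %in% ev$type)
  expect_false("AL" %in% ev$type)

  # AL is the mirror case on the minus strand (same coordinates)
  b1 <- transcript_model("b1", "g", "chr1", "-",
                         cbind(c(0, 600), c(100, 700)))
  b2 <- transcript_model("b2", "g", "chr1", "-",
                         cbind(c(300, 600), c(400, 700)))
  ev <- enumerate_events(build_annotation(list(b1, b2)))
  expect_true("AL" %in% ev$type)
  expect_false("AF" %in% ev$type)
})

test_that("enumeration equals the exhaustive pairwise oracle", {
  set.seed(31)
  for (rep in 1:40) {
    strand <- sample(c("+", "-"), 1)
    txs <- random_gene_tx("g", "chr1", strand, 1000, sample(2:6, 1),
                          n_exons = sample(4:7, 1))
    if (length(txs) < 2) next
    ev <- enumerate_events(build_annotation(txs))
    expect_equal(pkg_event_set(ev), oracle_events(txs, strand),
                 info = paste("rep", rep))
  }
})

test_that("duplicate genes do not change counts and novelty is propagated", {
  ann <- se_fixture()
  ev1 <- enumerate_events(ann)
  # adding an identical isoform set under a second enumeration pass
  ev2 <- enumerate_events(ann)
  expect_equal(count_events(ev1), count_events(ev2))

  ev_n <- enumerate_events(ann, novel_ids = "t2")
  expect_true(all(ev_n$novelty == "novel"))
  ev_k <- enumerate_events(ann, novel_ids = "unrelated")
  expect_true(all(ev_k$novelty == "known"))
})

test_that("mixed-strand genes are rejected by name", {
  t1 <- transcript_model("t1", "gX", "chr1", "+", cbind(c(0, 200), c(100, 300)))
  t2 <- transcript_model("t2", "gX", "chr1", "-", cbind(c(0, 200), c(100, 300)))
  expect_error(build_annotation(list(t1, t2)), "gX")
})

test_that("merge_observed attributes observed transcripts to called genes", {
  ann <- se_fixture()
  obs <- list(transcript_model("o1", "o1", "chr1", "+",
                               cbind(c(0, 200, 400), c(100, 250, 500))))
  calls <- classify_batch(obs, ann)$calls
  mo <- merge_observed(ann, obs, calls)
  expect_true("o1" %in% names(mo$annotation$tx))
  expect_equal(unname(mo$annotation$tx_gene[["o1"]]), "g")
  expect_equal(mo$novel_ids, "o1")
  ev <- enumerate_events(mo$annotation, mo$novel_ids)
  expect_true(any(ev$novelty == "novel"))
  expect_true(any(ev$novelty == "known"))
})
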