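# Hand-written locus used for the rule-by-rule examples:
# gene A (+): tA1 = three exons, tA2 = first two exons of tA1
# gene B (+): mono-exonic reference, downstream of A
# gene C (-): single transcript on the minus strand
fixture_ann <- function() {
  tA1 <- transcript_model("tA1", "gA", "chr1", "+",
                          cbind(c(100, 500, 900), c(200, 600, 1000)))
  tA2 <- transcript_model("tA2", "gA", "chr1", "+",
                          cbind(c(100, 500), c(200, 600)))
  tB <- transcript_model("tB", "gB", "chr1", "+", cbind(20000, 21000))
  tC <- transcript_model("tC", "gC", "chr1", "-",
                         cbind(c(40000, 41000), c(40500, 41600)))
  build_annotation(list(tA1, tA2, tB, tC))
}

test_that("the ordered rules reproduce the textbook cases", {
  ann <- fixture_ann()
  cl <- function(q) classify_transcript(q, ann)

  # FSM: identical chain, terminal ends free
  q <- transcript_model("q", "x", "chr1", "+",
                        cbind(c(130, 500, 900), c(200, 600, 980)))
  expect_equal(cl(q)$category, "FSM")
  expect_equal(cl(q)$matched_transcript_id, "tA1")

  # ISM: junction sub-chain (reference minus first exon)
  q <- transcript_model("q", "x", "chr1", "+",
                        cbind(c(520, 900), c(600, 1000)))
  expect_equal(cl(q)$category, "ISM")

  # NIC: skipping the internal exon joins annotated donor + acceptor
  q <- transcript_model("q", "x", "chr1", "+",
                        cbind(c(100, 900), c(200, 1000)))
  expect_equal(cl(q)$category, "NIC")

  # NNC: donor shifted +6 bp off any annotated donor
  q <- transcript_model("q", "x", "chr1", "+",
                        cbind(c(100, 500, 900), c(206, 600, 1000)))
  r <- cl(q)
  expect_equal(r$category, "NNC")
  expect_equal(r$novel_donors, 1)
  expect_equal(r$known_acceptors, 2)

  # antisense: opposite strand of a single-gene locus
  q <- transcript_model("q", "x", "chr1", "-",
                        cbind(c(100, 500), c(200, 600)))
  expect_equal(cl(q)$category, "antisense")

  # mono-exonic contained in a reference exon -> FSM
  q <- transcript_model("q", "x", "chr1", "+", cbind(20100, 20500))
  expect_equal(cl(q)$category, "FSM")
  expect_equal(cl(q)$matched_transcript_id, "tB")

  # mono-exonic matching a mono-exonic reference within 50 bp
  q <- transcript_model("q", "x", "chr1", "+", cbind(19960, 21040))
  expect_equal(cl(q)$category, "FSM")

  # mono-exonic fully inside an annotated intron
  q <- transcript_model("q", "x", "chr1", "+", cbind(250, 450))
  expect_equal(cl(q)$category, "genic_intron")

  # mono-exonic straddling exon and intron -> genic
  q <- transcript_model("q", "x", "chr1", "+", cbind(150, 450))
  expect_equal(cl(q)$category, "genic")

  # no overlap with any gene span
  q <- transcript_model("q", "x", "chr1", "+", cbind(80000, 80300))
  expect_equal(cl(q)$category, "intergenic")
})

test_that("fusion requires exonic overlap of two genes and a bridge", {
  tA <- transcript_model("tA", "gA", "chr1", "+",
                         cbind(c(100, 500), c(200, 600)))
  tB <- transcript_model("tB", "gB", "chr1", "+",
                         cbind(c(5000, 5500), c(5100, 5600)))
  ann <- build_annotation(list(tA, tB))
  q <- transcript_model("q", "x", "chr1", "+",
                        cbind(c(100, 500, 5000), c(200, 600, 5100)))
  r <- classify_transcript(q, ann)
  expect_equal(r$category, "fusion")
  expect_equal(r$matched_gene_id, "gA,gB")
})

test_that("FSM is invariant to terminal exon end coordinates", {
  ann <- fixture_ann()
  set.seed(7)
  for (i in 1:20) {
    d <- sample(-60:60, 2)
    q <- transcript_model("q", "x", "chr1", "+",
                          cbind(c(100 + d[1], 500, 900),
                                c(200, 600, max(910, 1000 + d[2]))))
    expect_equal(classify_transcript(q, ann)$category, "FSM")
  }
})

test_that("classification is exhaustive and exclusive on random fixtures", {
  set.seed(8)
  loc <- random_locus(4)
  qs <- lapply(1:50, function(i) random_query(loc$refs))
  cb <- classify_batch(qs, loc$ann)
  expect_equal(nrow(cb$calls), 50)
  expect_true(all(cb$calls$category %in%
                    c("FSM", "ISM", "NIC", "NNC", "fusion", "genic",
                      "antisense", "intergenic", "genic_intron")))
})

test_that("classify agrees with the brute-force oracle on random fixtures", {
  set.seed(9)
  for (rep in 1:60) {
    loc <- random_locus(sample(2:4, 1))
    for (j in 1:5) {
      q <- random_query(loc$refs)
      expect_equal(classify_transcript(q, loc$ann)$category,
                   oracle_classify(q, loc$refs),
                   info = sprintf("rep %d query %d", rep, j))
    }
  }
})

test_that("batch length summaries use linear-interpolation quantiles", {
  ann <- fixture_ann()
  q1 <- transcript_model("q1", "x", "chr1", "+", cbind(20100, 20600))
  cb <- classify_batch(list(q1), ann)
  expect_equal(cb$summary$category, "FSM")
  expect_equal(cb$summary$median, 500)
  expect_equal(cb$summary$n, 1)
  # absent categories do not appear
  expect_false("NNC" %in% cb$summary$category)
})
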