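test_that("mnemonic BED parsing preserves rows and validates input", {
  vocab <- roadmap15_vocabulary()
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t200\tTx", "chr1\t200\t400\tTx",
               "chr1\t400\t600\tQuies"), f)
  tr <- read_state_bed(f, vocab, sample_id = "s1")
  expect_s3_class(tr, "StateTrack")
  expect_equal(nrow(tr$intervals), 3L)  # same-state neighbours not merged
  expect_equal(tr$intervals$state, c("Tx", "Tx", "Quies"))
  expect_equal(tr$intervals$start, c(0, 200, 400))

  writeLines(c("chr1\t0\t200\tTx", "chr1\t200\t400\tFooBar"), f)
  expect_error(read_state_bed(f, vocab), "unknown state 'FooBar'.*line 2")

  writeLines(c("chr1\t0\t200\tTx", "chr1\t100\t300\tQuies"), f)
  expect_error(read_state_bed(f, vocab), "overlap")

  writeLines("chr1\tzero\t200\tTx", f)
  expect_error(read_state_bed(f, vocab), "malformed")

  file.create(f2 <- withr::local_tempfile(fileext = ".bed"))
  expect_equal(nrow(read_state_bed(f2, vocab)$intervals), 0L)
})

test_that("gzip-compressed BED input is accepted", {
  vocab <- roadmap15_vocabulary()
  f <- withr::local_tempfile(fileext = ".bed.gz")
  con <- gzfile(f, "w")
  writeLines(c("chr2\t0\t200\tEnh", "chr2\t200\t400\tHet"), con)
  close(con)
  tr <- read_state_bed(f, vocab)
  expect_equal(tr$intervals$state, c("Enh", "Het"))
})

test_that("write/read round-trips a track", {
  vocab <- toy_vocab()
  set.seed(3)
  tr <- grid_track("s1", sample(vocab$states, 50, replace = TRUE), vocab)
  f <- withr::local_tempfile(fileext = ".bed")
  write_state_bed(tr, f)
  back <- read_state_bed(f, vocab, sample_id = "s1")
  expect_equal(back$intervals, tr$intervals)
})

test_that("state_track enforces its invariants", {
  vocab <- toy_vocab()
  expect_error(state_track("s", "chr1", 100, 100, "Tx", vocab),
               "start >= end")
  expect_error(state_track("s", "chr1", -5, 100, "Tx", vocab),
               "malformed")
  expect_error(state_track("s", "chr1", 0, 100, "Nope", vocab),
               "unknown state")
  # unsorted input is sorted on construction
  tr <- state_track("s", c("chr1", "chr1"), c(200, 0), c(400, 200),
                    c("Enh", "Tx"), vocab)
  expect_equal(tr$intervals$start, c(0, 200))
})

test_that("reductions substitute states and validate coverage", {
  vocab <- toy_vocab()
  bin <- state_vocabulary(c("active", "inactive"), name = "bin")
  red <- state_reduction(vocab, bin,
                         c(Tx = "active", Enh = "active",
                           Het = "inactive", Quies = "inactive"))
  tr <- grid_track("s", c("Tx", "Quies", "Enh"), vocab)
  out <- reduce_track(tr, red)
  expect_equal(out$intervals$state, c("active", "inactive", "active"))
  expect_equal(out$intervals[, 1:3], tr$intervals[, 1:3])

  ident <- state_reduction(vocab, vocab,
                           stats::setNames(vocab$states, vocab$states))
  expect_equal(reduce_track(tr, ident)$intervals, tr$intervals)

  # shared target: two sources map to one label
  r15 <- roadmap_reduction(5)
  t15 <- grid_track("s", c("TssA", "TssAFlnk"), roadmap15_vocabulary())
  expect_equal(reduce_track(t15, r15)$intervals$state, c("TSS", "TSS"))
})

test_that("load_reduction rejects incomplete or conflicting maps", {
  vocab <- toy_vocab()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Tx\tactive", "Enh\tactive", "Het\tinactive"), f)
  expect_error(load_reduction(f, vocab), "uncovered states.*Quies")
  writeLines(c("Tx\tactive", "Tx\tinactive", "Enh\tactive",
               "Het\tinactive", "Quies\tinactive"), f)
  expect_error(load_reduction(f, vocab), "conflicting")
  writeLines(c("Tx\tactive", "Enh\tactive", "Het\tinactive",
               "Quies\tinactive"), f)
  expect_s3_class(load_reduction(f, vocab), "StateReduction")
})

test_that("reducing 15->5 then 5->2 equals the composed 15->2 map", {
  r5 <- roadmap_reduction(5)
  r2 <- roadmap_reduction(2)
  bin <- r2$target_vocab
  five2two <- state_reduction(
    r5$target_vocab, bin,
    c(TSS = "active", transcription = "active", enhancer = "active",
      bivalent = "inactive", heterochromatin = "inactive"))
  composed <- compose_reductions(r5, five2two)
  set.seed(11)
  tr <- grid_track("s", sample(roadmap15_vocabulary()$states, 100,
                               replace = TRUE), roadmap15_vocabulary())
  via_steps <- reduce_track(reduce_track(tr, r5), five2two)
  via_composed <- reduce_track(tr, composed)
  expect_equal(via_steps$intervals$state, via_composed$intervals$state)
  # the bundled direct 15->2 map agrees with the composition
  expect_equal(reduce_track(tr, r2)$intervals$state,
               via_composed$intervals$state)
})

test_that("vocabulary invariants hold", {
  expect_error(state_vocabulary(c("a", "a")), "duplicate")
  expect_error(state_vocabulary(c("a", "")), "non-empty")
  expect_error(state_vocabulary(c("a", "undefined")), "reserved")
  v <- roadmap15_vocabulary()
  expect_length(v$states, 15L)
  expect_false(v$undefined %in% v$states)
})

test_that("genome layout and chrom.sizes round-trip", {
  lay <- genome_layout(c("chr1", "chr2"), c(1e6, 250000))
  f <- withr::local_tempfile(fileext = ".sizes")
  write_chrom_sizes(lay, f)
  expect_false(any(grepl("e\\+", readLines(f))))  # no scientific notation
  back <- read_chrom_sizes(f)
  expect_equal(back$chrom, lay$chrom)
  expect_equal(back$length, lay$length)
  expect_error(genome_layout(c("chr1", "chr1"), c(1, 2)), "duplicate")
  expect_error(genome_layout("chr1", 0), "positive")
})
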