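test_that("median/MAD normalization matches hand-computed values", {
  rd <- raw_read("r1", c(1, 2, 3, 4, 100))
  out <- normalize_read(rd, clip = 5)
  expect_equal(out$params$shift, 3)
  expect_equal(out$params$scale, 1)
  expect_equal(out$samples, c(-2, -1, 0, 1, 5))  # 97 clipped to +5
})

test_that("an already-normalized signal passes through unchanged", {
  rd <- raw_read("r1", c(-1, 0, 1))
  out <- normalize_read(rd)
  expect_equal(out$params$shift, 0)
  expect_equal(out$params$scale, 1)
  expect_equal(out$samples, c(-1, 0, 1))
})

test_that("constant signal (MAD = 0) is a degenerate-signal error", {
  rd <- raw_read("bad_read", c(7, 7, 7))
  expect_error(normalize_read(rd), "degenerate signal.*bad_read")
})

test_that("normalization uses only the mapped span", {
  rd <- raw_read("r1", c(1000, 1, 2, 3, 4, 5, -1000))
  out <- normalize_read(rd, mapped_span = c(1L, 6L))
  expect_equal(out$params$shift, 3)
  expect_equal(out$params$scale, 1)
  expect_equal(out$samples, c(-2, -1, 0, 1, 2))
})

test_that("pre-clip normalized spans have median 0 and MAD 1", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(50:300, 1)
    rd <- raw_read(paste0("r", i), rnorm(n, mean = runif(1, 60, 120),
                                         sd = runif(1, 1, 15)))
    out <- normalize_read(rd, clip = 5)
    z <- (rd$samples - out$params$shift) / out$params$scale
    expect_lt(abs(median(z)), 1e-9)
    expect_lt(abs(median(abs(z - median(z))) - 1), 1e-9)
    expect_true(all(out$samples >= -5 & out$samples <= 5))
  }
})

test_that("a +1 base shift moves an f5c-style assignment onto the Tombo base", {
  # 5-mer CUAAG: the event sits on the first base (C) in the f5c convention
  # and on the second (U) in the Tombo convention
  tb <- event_table("r1", "BASECALL",
                    data.frame(position = 0L, start = 0L, length = 10L))
  shift <- resolve_base_shift("f5c_resquiggle", "RNA", "r9.4.1")
  expect_identical(shift, 1L)
  shifted <- apply_base_shift(tb, shift = shift, n_positions = 5L)
  expect_equal(shifted$events$position, 1L)
  expect_equal(shifted$events[, c("start", "length")],
               tb$events[, c("start", "length")])
})

test_that("shift 0 is the identity", {
  tb <- event_table("r1", "BASECALL",
                    data.frame(position = 0:2, start = c(0L, 4L, 9L),
                               length = c(4L, 5L, 2L)))
  expect_equal(apply_base_shift(tb, shift = 0L), tb)
})

test_that("events shifted outside the read are dropped", {
  tb <- event_table("r1", "BASECALL",
                    data.frame(position = 0:2, start = c(0L, 4L, 9L),
                               length = c(4L, 5L, 2L)))
  shifted <- apply_base_shift(tb, shift = 2L, n_positions = 3L)
  expect_equal(shifted$events$position, 2L)
  expect_equal(shifted$events$start, 0L)
})

test_that("'auto' with an unknown pore combination is a configuration error", {
  tb <- event_table("r1", "BASECALL",
                    data.frame(position = 0L, start = 0L, length = 3L))
  expect_error(
    apply_base_shift(tb, shift = "auto", dialect = "f5c_resquiggle",
                     molecule = "DNA", pore = "r12.9.9"),
    "configuration error")
})

test_that("RNA reversal flips signal and event intervals", {
  rd <- raw_read("r1", 1:10, molecule = "RNA")
  tb <- event_table("r1", "BASECALL",
                    data.frame(position = 0L, start = 7L, length = 3L))
  flipped <- reverse_rna_events(rd, tb)
  expect_equal(flipped$table$events$start, 0L)
  expect_equal(flipped$table$events$length, 3L)
  expect_equal(flipped$read$samples, rev(rd$samples))
})

test_that("RNA reversal is an involution", {
  set.seed(5)
  rd <- raw_read("r1", rnorm(30), molecule = "RNA")
  # positions ascend while starts descend: a 3'->5'-stored signal
  tb <- event_table("r1", "BASECALL",
                    data.frame(position = 0:2, start = c(20L, 12L, 0L),
                               length = c(10L, 8L, 12L)))
  twice <- with(reverse_rna_events(rd, tb),
                reverse_rna_events(read, table))
  expect_equal(twice$read$samples, rd$samples)
  expect_equal(twice$table$events, tb$events)
})

test_that("RNA reversal refuses DNA reads and an event covering all samples keeps start 0", {
  rd_dna <- raw_read("r1", 1:10, molecule = "DNA")
  tb <- event_table("r1", "BASECALL",
                    data.frame(position = 0L, start = 0L, length = 10L))
  expect_error(reverse_rna_events(rd_dna, tb), "RNA")
  rd_rna <- raw_read("r1", 1:10, molecule = "RNA")
  expect_equal(reverse_rna_events(rd_rna, tb)$table$events$start, 0L)
})

basecall_events <- function(positions) {
  event_table("r1", "BASECALL",
              data.frame(position = positions,
                         start = 3L * positions, length = 3L))
}

test_that("collinear forward projection is position + ref_start", {
  tb <- basecall_events(0:4)
  proj <- project_to_reference(tb, list(contig = "c", ref_start = 100L,
                                        cigar = "5M", strand = "+"))
  expect_equal(proj$events$ref_position, 100:104)
  expect_equal(proj$events$start, tb$events$start)
})

test_that("insertions drop events and shift later ones", {
  tb <- basecall_events(0:4)
  proj <- project_to_reference(tb, list(contig = "c", ref_start = 100L,
                                        cigar = "2M1I2M", strand = "+"))
  # basecall 2 is the inserted base: dropped; basecall 3 -> ref 102
  expect_equal(proj$events$ref_position, c(100L, 101L, 102L, 103L))
  expect_false(6L %in% proj$events$start)
})

test_that("soft clips offset the basecall index", {
  tb <- basecall_events(0:6)
  proj <- project_to_reference(tb, list(contig = "c", ref_start = 50L,
                                        cigar = "3S4M", strand = "+"))
  expect_equal(proj$events$ref_position, 50:53)
  expect_equal(proj$events$start, 3L * (3:6))
})

test_that("event positions beyond the query raise an inconsistency error", {
  tb <- basecall_events(0:9)
  expect_error(
    project_to_reference(tb, list(contig = "c", ref_start = 0L,
                                  cigar = "5M", strand = "+")),
    "inconsistency.*r1")
})

test_that("projection matches the per-base expansion oracle on random CIGARs", {
  set.seed(2024)
  for (rep in 1:200) {
    cigar <- random_cigar()
    oracle <- oracle_query_ref_columns(cigar, ref_start = 500L)
    strand <- sample(c("+", "-"), 1)
    positions <- sort(sample(0:(oracle$qlen - 1L),
                             sample(1:oracle$qlen, 1)))
    tb <- event_table("r1", "BASECALL",
                      data.frame(position = positions,
                                 start = 2L * positions, length = 2L))
    proj <- project_to_reference(tb, list(contig = "c", ref_start = 500L,
                                          cigar = cigar, strand = strand))
    qidx <- if (strand == "-") oracle$qlen - 1L - positions else positions
    expected_ref <- oracle$ref[qidx + 1L]
    keep <- !is.na(expected_ref)
    expect_identical(proj$events$ref_position, expected_ref[keep])
    expect_identical(proj$events$start, 2L * positions[keep])
    # conservation: projected + dropped-on-insertion = input
    expect_identical(nrow(proj$events) + sum(!keep), length(positions))
  }
})
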