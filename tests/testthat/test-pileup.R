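qual40 <- function(n) strrep("I", n)

test_that("direct counting: matched bases accumulate per position", {
  reads <- tibble::tibble(
    qname = paste0("r", 1:5), flag = 0L, rname = "c1", pos = 100L,
    mapq = 60L, cigar = "1M", seq = "C", qual = "I")
  sam <- write_sam(tempfile(fileext = ".sam"), c(c1 = 300L), reads)
  pu <- build_pileup(sam)
  expect_equal(nrow(pu), 1L)
  expect_equal(pu$pos, 100L)
  expect_equal(pu$C, 5L)
  expect_equal(pu$coverage, 5L)
})

test_that("deletions consume reference but contribute no counts", {
  reads <- tibble::tibble(
    qname = "r1", flag = 0L, rname = "c1", pos = 10L, mapq = 60L,
    cigar = "2M1D2M", seq = "ACGT", qual = qual40(4))
  sam <- write_sam(tempfile(fileext = ".sam"), c(c1 = 300L), reads)
  pu <- build_pileup(sam)
  expect_equal(pu$pos, c(10L, 11L, 13L, 14L))
  expect_equal(pu$coverage, rep(1L, 4))
})

test_that("quality cutoffs exclude bases and reads from counts and coverage", {
  reads <- tibble::tibble(
    qname = c("hi", "lowbq", "lowmq"), flag = 0L, rname = "c1",
    pos = 50L, mapq = c(60L, 60L, 5L), cigar = "2M",
    seq = "AC", qual = c(qual40(2), "I#", qual40(2)))
  sam <- write_sam(tempfile(fileext = ".sam"), c(c1 = 300L), reads)
  pu <- build_pileup(sam, min_base_quality = 25, min_mapping_quality = 10)
  # pos 50: two passing 'A's; pos 51: lowbq base '#' dropped -> one 'C'
  expect_equal(pu$A[pu$pos == 50], 2L)
  expect_equal(pu$coverage[pu$pos == 51], 1L)
})

random_sam <- function(path, n_reads = 1000, contig_len = 2000) {
  starts <- sample(contig_len - 60L, n_reads, replace = TRUE)
  cigars <- character(n_reads)
  seqs <- character(n_reads)
  quals <- character(n_reads)
  for (i in seq_len(n_reads)) {
    kind <- sample(3, 1)
    if (kind == 1) {           # plain match
      L <- sample(20:40, 1)
      cigars[i] <- paste0(L, "M")
    } else if (kind == 2) {    # deletion in the middle
      a <- sample(5:15, 1); d <- sample(1:5, 1); b <- sample(5:15, 1)
      cigars[i] <- paste0(a, "M", d, "D", b, "M")
      L <- a + b
    } else {                   # insertion in the middle
      a <- sample(5:15, 1); ins <- sample(1:4, 1); b <- sample(5:15, 1)
      cigars[i] <- paste0(a, "M", ins, "I", b, "M")
      L <- a + ins + b
    }
    seqs[i] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                     collapse = "")
    # mixed qualities around the cutoff
    quals[i] <- intToUtf8(33L + sample(c(20L, 30L, 40L), L, replace = TRUE))
  }
  reads <- tibble::tibble(qname = paste0("r", seq_len(n_reads)), flag = 0L,
                          rname = "c1", pos = starts,
                          mapq = sample(c(0L, 30L, 60L), n_reads, TRUE),
                          cigar = cigars, seq = seqs, qual = quals)
  write_sam(path, c(c1 = contig_len + 100L), reads)
}

test_that("build_pileup matches the naive per-read walker on random reads", {
  withr::with_seed(42, {
    sam <- random_sam(tempfile(fileext = ".sam"))
  })
  got <- build_pileup(sam, min_base_quality = 25, min_mapping_quality = 10)
  want <- naive_pileup(sam, min_bq = 25, min_mq = 10)
  expect_equal(as.data.frame(got), as.data.frame(want))
  # total coverage equals total counted aligned bases
  expect_equal(sum(got$coverage), sum(want$A + want$C + want$G + want$T))
})

test_that("counting is order-independent and zero-pass input yields empty", {
  withr::with_seed(7, sam <- random_sam(tempfile(fileext = ".sam"),
                                        n_reads = 200))
  lines <- readLines(sam)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  shuf <- tempfile(fileext = ".sam")
  writeLines(c(hdr, sample(body)), shuf)
  expect_equal(as.data.frame(build_pileup(sam)),
               as.data.frame(build_pileup(shuf)))

  # all bases below the quality threshold -> empty matrix
  reads <- tibble::tibble(qname = "r1", flag = 0L, rname = "c1", pos = 5L,
                          mapq = 60L, cigar = "3M", seq = "ACG", qual = "###")
  low <- write_sam(tempfile(fileext = ".sam"), c(c1 = 100L), reads)
  expect_equal(nrow(build_pileup(low)), 0L)
})

test_that("pooling sums counts element-wise and is fold-left associative", {
  a <- pileup_tbl("c1", 5L, A = 0L, C = 3L, G = 0L, T = 0L)
  b <- pileup_tbl("c1", 5L, A = 0L, C = 2L, G = 0L, T = 1L)
  ab <- pool_pileups(list(a, b))
  expect_equal(ab$C, 5L)
  expect_equal(ab$T, 1L)
  expect_equal(ab$coverage, 6L)

  expect_equal(as.data.frame(pool_pileups(list(a, pileup_tbl()))),
               as.data.frame(a))

  withr::with_seed(11, {
    idx <- toy_index()
    ms <- replicate(3, random_pileup(idx), simplify = FALSE)
  })
  all3 <- pool_pileups(ms)
  fold <- pool_pileups(list(pool_pileups(list(ms[[1]], ms[[2]])), ms[[3]]))
  expect_equal(as.data.frame(all3), as.data.frame(fold))

  expect_error(pool_pileups(list()), "non-empty")
})

test_that("pileup TSV round-trips exactly, including edge cases", {
  # empty
  p0 <- pileup_tbl()
  f0 <- tempfile(fileext = ".tsv")
  write_pileup(p0, f0)
  expect_equal(nrow(read_pileup(f0)), 0L)
  expect_true(startsWith(readLines(f0)[1], "#"))

  # single record
  p1 <- pileup_tbl("c2", 17L, 1L, 2L, 3L, 4L)
  f1 <- tempfile(fileext = ".tsv")
  write_pileup(p1, f1)
  expect_equal(as.data.frame(read_pileup(f1)), as.data.frame(p1))

  # large random matrix
  withr::with_seed(3, {
    n <- 10000L
    pos <- sort(sample.int(5e6, n))
    m <- matrix(sample(0:50, 4 * n, replace = TRUE), ncol = 4)
  })
  pbig <- pileup_tbl(rep("chrR", n), pos, m[, 1], m[, 2], m[, 3], m[, 4])
  fbig <- tempfile(fileext = ".tsv")
  write_pileup(pbig, fbig)
  expect_equal(as.data.frame(read_pileup(fbig)), as.data.frame(pbig))
})

test_that("malformed pileup lines are rejected with a line number", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("#header", "c1\t5\t1\t2\t3\t4\t10", "c1\t6\t1\t2"), f)
  expect_error(read_pileup(f), "line 3")
  writeLines(c("#header", "c1\t5\t1\tx\t3\t4\t8"), f)
  expect_error(read_pileup(f), "line 2")
})
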