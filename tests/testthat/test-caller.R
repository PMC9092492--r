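# single plus-strand position inside the CDS of the toy annotation
pu1 <- function(C, T, pos = 180L) {
  pileup_tbl("c1", pos, A = 0L, C = as.integer(C), G = 0L, T = as.integer(T))
}

test_that("edit ratio is n_alt over informative reads", {
  expect_equal(compute_edit_ratio(8, 2), 0.20)
  expect_equal(compute_edit_ratio(0, 5), 1.0)
  expect_error(compute_edit_ratio(0, 0), "undefined")
})

test_that("worked example: enriched site is called with fold 4", {
  idx <- toy_index()
  out <- call_sites(pu1(16, 4), pu1(19, 1), idx)
  expect_equal(nrow(out), 1L)
  expect_equal(out$edit_ratio, 0.20)
  expect_equal(out$control_ratio, 0.05)
  expect_equal(out$fold, 4.0)
  expect_equal(out$ref, "C")
  expect_equal(out$alt, "T")
  expect_equal(out$region, "CDS")
})

test_that("coverage threshold: 9 informative reads fail, 10 pass", {
  idx <- toy_index()
  ctl <- pu1(50, 0)
  expect_equal(nrow(call_sites(pu1(7, 2), ctl, idx)), 0L)
  expect_equal(nrow(call_sites(pu1(8, 2), ctl, idx)), 1L)
})

test_that("edit-ratio bounds are inclusive at 0.05 and 0.95", {
  idx <- toy_index()
  ctl <- pu1(100, 0)
  expect_equal(nrow(call_sites(pu1(96, 4), ctl, idx)), 0L)    # 0.04
  expect_equal(nrow(call_sites(pu1(95, 5), ctl, idx)), 1L)    # 0.05
  expect_equal(nrow(call_sites(pu1(5, 95), ctl, idx)), 1L)    # 0.95
  expect_equal(nrow(call_sites(pu1(4, 96), ctl, idx)), 0L)    # 0.96
})

test_that("fold threshold: 1.19x fails, 1.20x passes", {
  idx <- toy_index()
  ctl <- pu1(800, 200)                                        # ratio 0.20
  expect_equal(nrow(call_sites(pu1(762, 238), ctl, idx)), 0L) # fold 1.19
  expect_equal(nrow(call_sites(pu1(760, 240), ctl, idx)), 1L) # fold 1.20
  # a modestly enriched site below 1.2x is rejected
  expect_equal(nrow(call_sites(pu1(80, 20), pu1(82, 18), idx)), 0L)
})

test_that("minimum edited reads: 1 fails, 2 pass", {
  idx <- toy_index()
  ctl <- pu1(50, 0)
  expect_equal(nrow(call_sites(pu1(19, 1), ctl, idx)), 0L)
  expect_equal(nrow(call_sites(pu1(18, 2), ctl, idx)), 1L)
})

test_that("control coverage gates callability; zero control editing passes", {
  idx <- toy_index()
  expect_equal(nrow(call_sites(pu1(16, 4), pu1(9, 0), idx)), 0L)
  out <- call_sites(pu1(16, 4), pu1(10, 0), idx)
  expect_equal(nrow(out), 1L)
  expect_equal(out$control_ratio, 0)
  expect_true(is.infinite(out$fold))
  # missing control position entirely -> not callable
  expect_equal(nrow(call_sites(pu1(16, 4), pu1(50, 0, pos = 190L), idx)), 0L)
})

test_that("positions outside annotated genes are never called", {
  idx <- toy_index()
  out <- call_sites(pu1(16, 4, pos = 5000L), pu1(50, 0, pos = 5000L), idx)
  expect_equal(nrow(out), 0L)
})

test_that("strand correctness: minus-strand genes call G-to-A positions", {
  idx <- toy_index()
  # same counts placed at a minus-strand CDS position, as G/A
  sm <- pileup_tbl("c1", 1100L, A = 4L, C = 0L, G = 16L, T = 0L)
  cm <- pileup_tbl("c1", 1100L, A = 0L, C = 0L, G = 20L, T = 0L)
  out <- call_sites(sm, cm, idx)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ref, "G")
  expect_equal(out$alt, "A")
  expect_equal(out$strand, "-")
  expect_equal(out$edit_ratio, 0.2)
  # C/T counts at a minus-strand gene are not a C2U signal
  sp <- pileup_tbl("c1", 1100L, A = 0L, C = 16L, G = 0L, T = 4L)
  expect_equal(nrow(call_sites(sp, sp, idx)), 0L)
})

test_that("A2I mode uses A-to-G (T-to-C on minus-strand genes)", {
  idx <- toy_index()
  p <- caller_params(edit_type = "A2I")
  sa <- pileup_tbl("c1", 180L, A = 16L, C = 0L, G = 4L, T = 0L)
  ca <- pileup_tbl("c1", 180L, A = 20L, C = 0L, G = 0L, T = 0L)
  out <- call_sites(sa, ca, idx, p)
  expect_equal(out$ref, "A")
  expect_equal(out$alt, "G")
  st <- pileup_tbl("c1", 1100L, A = 0L, C = 4L, G = 0L, T = 16L)
  ct <- pileup_tbl("c1", 1100L, A = 0L, C = 0L, G = 0L, T = 20L)
  out2 <- call_sites(st, ct, idx, p)
  expect_equal(out2$ref, "T")
  expect_equal(out2$alt, "C")
  expect_equal(out2$edit_type, "A2I")
})

test_that("genome-aware calling skips positions whose ref base mismatches", {
  idx <- toy_index()
  g <- Biostrings::DNAStringSet(c(c1 = strrep("A", 2100)))
  # all-A genome: position 180 is not a reference C
  expect_equal(nrow(call_sites(pu1(16, 4), pu1(19, 1), idx,
                               genome = g)), 0L)
  g2 <- Biostrings::DNAStringSet(
    c(c1 = paste0(strrep("A", 179), "C", strrep("A", 1920))))
  expect_equal(nrow(call_sites(pu1(16, 4), pu1(19, 1), idx,
                               genome = g2)), 1L)
})

test_that("self-null: calling a matrix against itself yields nothing", {
  idx <- toy_index()
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- random_pileup(idx)
      expect_equal(nrow(call_sites(m, m, idx)), 0L)
    }
  })
})

test_that("tightening any threshold never increases the called set", {
  idx <- toy_index()
  withr::with_seed(9, {
    sm <- random_pileup(idx, n = 600)
    cm <- random_pileup(idx, n = 600)
  })
  base <- nrow(call_sites(sm, cm, idx, caller_params(min_fold = 1)))
  tighter <- list(
    caller_params(min_coverage = 20, min_fold = 1),
    caller_params(min_alt_reads = 5, min_fold = 1),
    caller_params(min_fold = 1.5),
    caller_params(ratio_low = 0.2, ratio_high = 0.8, min_fold = 1))
  for (p in tighter) {
    expect_lte(nrow(call_sites(sm, cm, idx, p)), base)
  }
})

test_that("caller agrees with the brute-force oracle on random matrices", {
  idx <- toy_index()
  smap <- strand_map(idx)
  withr::with_seed(31, {
    for (i in 1:5) {
      sm <- random_pileup(idx, n = 500)
      cm <- random_pileup(idx, n = 500)
      got <- call_sites(sm, cm, idx, caller_params(min_fold = 1.0))
      want <- brute_caller(sm, cm, smap, caller_params(min_fold = 1.0))
      expect_equal(got$pos, want$pos)
      expect_equal(got$edit_ratio, want$edit_ratio)
      expect_equal(got$strand, unname(want$strand))
    }
  })
})

test_that("replicate merging keeps sites found in enough replicates", {
  idx <- toy_index()
  ctl <- pool_pileups(list(pu1(50, 0), pu1(50, 0, pos = 190L),
                           pu1(50, 0, pos = 195L)))
  siteA <- pu1(16, 4, pos = 180L)
  siteB <- pu1(16, 4, pos = 190L)
  siteC <- pu1(16, 4, pos = 195L)
  rep1 <- call_sites(pool_pileups(list(siteA, siteB)), ctl, idx)
  rep2 <- call_sites(pool_pileups(list(siteB, siteC)), ctl, idx)
  rep3 <- call_sites(siteB, ctl, idx)
  m <- merge_replicates(list(rep1, rep2, rep3), 2)
  expect_equal(m$pos, 190L)
  expect_equal(m$replicate_support, 3L)
  expect_equal(m$edit_ratio, 0.2)   # mean of identical per-replicate ratios

  # a site in only one replicate is removed, one in two is kept
  m2 <- merge_replicates(list(rep1, call_sites(siteA, ctl, idx),
                              call_sites(pileup_tbl(), ctl, idx)), 2)
  expect_equal(m2$pos, 180L)

  empties <- replicate(3, call_sites(pileup_tbl(), ctl, idx),
                       simplify = FALSE)
  expect_equal(nrow(merge_replicates(empties, 2)), 0L)

  a2i <- call_sites(pileup_tbl("c1", 180L, A = 16L, C = 0L, G = 4L, T = 0L),
                    pileup_tbl("c1", 180L, A = 20L, C = 0L, G = 0L, T = 0L),
                    idx, caller_params(edit_type = "A2I"))
  expect_error(merge_replicates(list(rep1, a2i), 2), "edit type")
})
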