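small_cfg <- function(...) {
  args <- list(n_genes = 8L, n_true_sites = 24L, n_artifact_sites = 4L,
               n_replicates = 2L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

test_that("simulated references are valid, self-consistent and seeded", {
  ref <- simulate_reference(small_cfg(), seed = 5)
  expect_equal(nrow(ref$truth), 24L)
  expect_equal(nrow(ref$artifacts), 4L)
  # GTF written and re-read reproduces region lengths
  d <- tempfile(); dir.create(d)
  write_reference(ref, d)
  idx2 <- read_annotation(file.path(d, "annotation.gtf"))
  orig <- dplyr::arrange(ref$index$transcripts, transcript_id)
  back <- dplyr::arrange(idx2$transcripts, transcript_id)
  expect_equal(back$utr5_len, orig$utr5_len)
  expect_equal(back$cds_len, orig$cds_len)
  expect_equal(back$utr3_len, orig$utr3_len)
  # FASTA round-trips
  g2 <- load_genome(file.path(d, "genome.fa"))
  expect_equal(as.character(g2), as.character(ref$genome))

  # byte-identical regeneration under the same seed
  d2 <- tempfile(); dir.create(d2)
  write_reference(simulate_reference(small_cfg(), seed = 5), d2)
  for (f in c("genome.fa", "annotation.gtf", "truth.tsv")) {
    expect_identical(readLines(file.path(d, f)), readLines(file.path(d2, f)))
  }
})

test_that("an empty truth configuration still yields a valid reference", {
  ref <- simulate_reference(small_cfg(n_true_sites = 0L,
                                      n_artifact_sites = 0L), seed = 2)
  expect_equal(nrow(ref$truth), 0L)
  expect_gt(sum(Biostrings::width(ref$genome)), 0L)
  expect_equal(nrow(ref$index$transcripts), 8L)
})

test_that("every C2U truth site sits in an RAC transcript-strand context", {
  ref <- simulate_reference(small_cfg(), seed = 8)
  ctx <- motif_context(ref$truth, ref$genome, width = 3L)
  expect_true(all(oracle_rac_match(ctx)))
  # truth regions follow the configured 3'UTR bias qualitatively
  expect_gt(mean(ref$truth$region == "3UTR"), 0.3)
})

test_that("A2I truth sites are the methylated adenosines inside RAC", {
  ref <- simulate_reference(small_cfg(edit_type = "A2I"), seed = 8)
  # transcript-strand base at the site is A, with C immediately 3'
  p <- ref$positions
  key <- paste(p$contig, p$pos)
  tb <- p$tstrand_base[match(paste(ref$truth$contig, ref$truth$pos), key)]
  expect_true(all(tb == "A"))
})

test_that("pileup simulation follows the configured coverage and rates", {
  cfg <- small_cfg(background_rate = 0, n_true_sites = 0L,
                   n_artifact_sites = 0L)
  ref <- simulate_reference(cfg, seed = 3)
  pu <- simulate_pileups(ref, seed = 4, conditions = "dart")$dart[[1]]
  # no editing anywhere: every position carries a single base
  expect_true(all(rowSums(as.matrix(pu[, c("A", "C", "G", "T")]) > 0) == 1))

  # empirical mean coverage within 5% of the negative-binomial mean
  n_pos <- nrow(ref$positions)
  expect_gt(n_pos, 10000L)
  expect_lt(abs(mean(pu$coverage[match(
    paste(ref$positions$contig, ref$positions$pos),
    paste(pu$contig, pu$pos))], na.rm = TRUE) - 50) / 50, 0.05)
})

test_that("truth-site edit ratios reproduce the configured Beta law", {
  cfg <- sim_config(n_genes = 40L, n_true_sites = 400L,
                    n_artifact_sites = 0L, n_replicates = 1L,
                    coverage_mean = 2000, coverage_dispersion = 50,
                    background_rate = 0)
  ref <- simulate_reference(cfg, seed = 21)
  pu <- simulate_pileups(ref, seed = 22, conditions = "dart")$dart[[1]]
  key <- paste(pu$contig, pu$pos)
  i <- match(paste(ref$truth$contig, ref$truth$pos), key)
  eb <- dartseq:::edit_bases("C2U", ref$truth$strand)
  m <- as.matrix(pu[, c("A", "C", "G", "T")])
  n_ref <- m[cbind(i, match(eb$ref, colnames(m)))]
  n_alt <- m[cbind(i, match(eb$alt, colnames(m)))]
  ratio <- n_alt / (n_ref + n_alt)
  ks <- suppressWarnings(ks.test(ratio, pbeta, 3, 7))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated alignments reproduce the reference and rate model", {
  cfg <- sim_config(n_genes = 3L, n_true_sites = 6L, n_artifact_sites = 0L,
                    n_replicates = 1L, coverage_mean = 10,
                    background_rate = 0, exons_per_gene = c(1L, 2L))
  ref <- simulate_reference(cfg, seed = 6)
  d <- tempfile(); dir.create(d)

  # no editing: pileup of the reads matches the reference bases exactly
  cfg0 <- sim_config(n_genes = 2L, n_true_sites = 0L, n_artifact_sites = 0L,
                     n_replicates = 1L, coverage_mean = 5,
                     background_rate = 0, exons_per_gene = c(1L, 1L))
  ref0 <- simulate_reference(cfg0, seed = 7)
  sam0 <- simulate_alignments(ref0, d, seed = 8, conditions = "dart")$dart[1]
  pu0 <- build_pileup(sam0)
  base_at <- dartseq:::genome_base(ref0$genome, pu0$contig, pu0$pos)
  m0 <- as.matrix(pu0[, c("A", "C", "G", "T")])
  called <- colnames(m0)[max.col(m0)]
  expect_equal(called, base_at)

  # identical SAM bytes under the same seed
  d2 <- tempfile(); dir.create(d2)
  s1 <- simulate_alignments(ref, d, seed = 9, conditions = "dart")$dart[1]
  s2 <- simulate_alignments(ref, d2, seed = 9, conditions = "dart")$dart[1]
  expect_identical(readLines(s1), readLines(s2))
})

test_that("deep alignments concentrate per-site ratios near the truth", {
  cfg <- sim_config(n_genes = 4L, n_true_sites = 20L, n_artifact_sites = 0L,
                    n_replicates = 1L, coverage_mean = 200,
                    background_rate = 0, exons_per_gene = c(1L, 2L),
                    dart_rate_shape = c(2, 18))
  ref <- simulate_reference(cfg, seed = 31)
  d <- tempfile(); dir.create(d)
  sam <- simulate_alignments(ref, d, seed = 32, conditions = "dart")$dart[1]
  pu <- build_pileup(sam)
  key <- paste(pu$contig, pu$pos)
  i <- match(paste(ref$truth$contig, ref$truth$pos), key)
  eb <- dartseq:::edit_bases("C2U", ref$truth$strand)
  m <- as.matrix(pu[, c("A", "C", "G", "T")])
  n_ref <- m[cbind(i, match(eb$ref, colnames(m)))]
  n_alt <- m[cbind(i, match(eb$alt, colnames(m)))]
  ratio <- n_alt / (n_ref + n_alt)
  expect_gte(mean(abs(ratio - ref$truth$rate) <= 0.07), 0.9)
})

test_that("raising control residual editing monotonically removes sites", {
  counts <- integer()
  for (mult in c(0.05, 0.2, 0.4, 0.7, 1.0)) {
    cfg <- sim_config(n_genes = 20L, n_true_sites = 60L,
                      n_artifact_sites = 0L, n_replicates = 2L,
                      control_multiplier = mult)
    ref <- simulate_reference(cfg, seed = 51)
    pu <- simulate_pileups(ref, seed = 52,
                           conditions = c("dart", "control"))
    ctl <- pool_pileups(pu$control)
    reps <- lapply(pu$dart, call_sites, control = ctl, index = ref$index,
                   params = caller_params(), genome = ref$genome)
    counts <- c(counts, nrow(merge_replicates(reps, 2)))
  }
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[length(counts)], counts[1])
})
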