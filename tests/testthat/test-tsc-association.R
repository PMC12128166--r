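test_that("ld_prime handles independence and perfect association", {
  r <- ld_prime(10, 10, 10, 10)
  expect_equal(r$ld_raw, 0)
  expect_equal(r$ld_norm, 0)
  expect_true(r$defined)
  expect_equal(ld_prime(10, 0, 0, 10)$ld_norm, 1)
  expect_equal(ld_prime(0, 10, 10, 0)$ld_norm, -1)
  # zero margin: undefined, like the [[0,0],[10,4]] degenerate case
  r0 <- ld_prime(0, 0, 10, 4)
  expect_false(r0$defined)
  expect_true(is.na(r0$ld_norm))
  expect_error(ld_prime(0, 0, 0, 0), "all-zero")
})

test_that("chi-squared p matches hand-expanded statistics", {
  expect_equal(as.numeric(contingency_p(10, 10, 10, 10)), 1)
  # frozen from the n(ad-bc)^2 / (r1 r2 c1 c2) expansion, df 1
  expect_equal(as.numeric(contingency_p(22, 8, 25, 49, correction = FALSE)),
               2.410927e-4, tolerance = 1e-4)
  expect_equal(attr(contingency_p(22, 8, 25, 49, correction = FALSE),
                    "statistic"), 13.48021, tolerance = 1e-5)
  expect_equal(as.numeric(contingency_p(22, 8, 25, 49, correction = TRUE)),
               5.521494e-4, tolerance = 1e-4)
  # zero margin is flagged with p = 1
  p0 <- contingency_p(0, 0, 5, 7)
  expect_equal(as.numeric(p0), 1)
  expect_true(attr(p0, "flagged"))
})

test_that("chi-squared agrees with stats::chisq.test and is swap-invariant", {
  set.seed(3)
  for (i in 1:20) {
    t <- rmultinom(1, sample(20:200, 1), runif(4, 0.05, 1))
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    for (corr in c(TRUE, FALSE)) {
      mine <- as.numeric(contingency_p(a, b, c, d, corr))
      ref <- suppressWarnings(
        stats::chisq.test(matrix(c(a, c, b, d), 2), correct = corr)$p.value)
      expect_equal(mine, ref, tolerance = 1e-10)
      # simultaneous row and column swap leaves p unchanged
      expect_equal(as.numeric(contingency_p(d, c, b, a, corr)), mine,
                   tolerance = 1e-12)
    }
  }
})

test_that("bh_adjust reproduces the step-up formula", {
  r <- bh_adjust(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_equal(r$adjusted, rep(0.04, 4))
  expect_true(all(r$reject))
  expect_equal(bh_adjust(0.2)$adjusted, 0.2)
  expect_equal(bh_adjust(c(0, 0))$adjusted, c(0, 0))
})

test_that("bh_adjust matches p.adjust, is order-invariant and dominates Bonferroni", {
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    r <- bh_adjust(p, alpha = 0.05)
    expect_equal(r$adjusted, stats::p.adjust(p, "BH"))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm])$adjusted, r$adjusted[perm])
    bonf <- p * length(p) <= 0.05
    expect_true(all(r$reject[bonf]))
  }
})

test_that("binomial test matches the exact point-probability method", {
  expect_equal(binomial_direction_test(10, 10), 2 * 0.5^10)
  expect_equal(binomial_direction_test(5, 10), 1)
  expect_equal(binomial_direction_test(0, 1), 1)
  set.seed(8)
  for (i in 1:15) {
    n <- sample(1:60, 1)
    k <- sample(0:n, 1)
    p0 <- sample(c(0.3, 0.5, 0.7), 1)
    expect_equal(binomial_direction_test(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-12)
  }
})

test_that("window_contingency handles degenerate margins and empty windows", {
  genes <- make_genes(c(1000L, 3000L, 5000L, 7000L),
                      c(1900L, 3900L, 5900L, 7900L), rep("+", 4))
  shifts <- make_shifts(genes$gene_id, rep("up", 4))
  mods_b <- make_mods(genes$tsc_position - 50L, "+")  # one call each, upstream
  mods_a <- mods_b[0, ]
  r <- window_contingency(genes, mods_a, mods_b, shifts,
                          offset = -80L, window = 60L)
  expect_equal(c(r$a, r$b, r$c, r$d), c(4L, 0L, 0L, 0L))
  expect_false(r$ld_defined)
  # unchanged genes contribute nothing
  r2 <- window_contingency(genes, mods_b, mods_b, shifts,
                           offset = -80L, window = 60L)
  expect_equal(r2$n, 0L)
  expect_true(r2$flagged)
})

test_that("window_contingency equals an independent per-gene tally oracle", {
  set.seed(19)
  for (rep in 1:8) {
    n <- 40L
    starts <- seq(2000L, by = 2000L, length.out = n)
    strands <- sample(c("+", "-"), n, TRUE)
    genes <- make_genes(starts, starts + 999L, strands)
    shifts <- make_shifts(genes$gene_id,
                          sample(c("up", "down", "none"), n, TRUE))
    mpos <- sample.int(90000L, 600, TRUE)
    mods_a <- make_mods(mpos[1:300], sample(c("+", "-"), 300, TRUE),
                        score = runif(300, 0, 200))
    mods_b <- make_mods(mpos[301:600], sample(c("+", "-"), 300, TRUE),
                        score = runif(300, 0, 200))
    offset <- sample(-300:50, 1)
    window <- sample(c(27L, 40L, 87L), 1)
    cutoff <- sample(c(0, 50, 120), 1)
    got <- window_contingency(genes, mods_a, mods_b, shifts, offset, window,
                              score_cutoff = cutoff)
    want <- oracle_window_tally(genes, mods_a, mods_b, shifts, offset,
                                window, cutoff)
    expect_equal(c(got$a, got$b, got$c, got$d), unname(want))
  }
})

test_that("a single-point sweep is consistent with window_contingency", {
  set.seed(29)
  sc <- synthetic_scenario(genome_length = 100000L, n_genes = 60L,
                           seed = 29L)
  ds <- generate_linked_dataset(sc)
  cfg <- sweep_config(window_sizes = 36L, category_counts = 3L,
                      score_cutoffs = 100, offset_range = c(-120L, -120L),
                      window_step = 2L)
  sw <- association_sweep(ds$genes, ds$mods_a, ds$mods_b,
                          ds$counts_a, ds$counts_b, cfg, genome = ds$genome)
  expect_equal(nrow(sw$runs), 1L)
  pa <- expression_profile(ds$counts_a, ds$genes, k = 3)
  pb <- expression_profile(ds$counts_b, ds$genes, k = 3)
  sh <- category_shifts(pa, pb)
  wc <- window_contingency(ds$genes, ds$mods_a, ds$mods_b, sh,
                           offset = -120L, window = 36L, score_cutoff = 100,
                           contig_length = ds$genome$length, circular = TRUE)
  expect_equal(c(sw$runs$a, sw$runs$b, sw$runs$c, sw$runs$d),
               c(wc$a, wc$b, wc$c, wc$d))
  if (wc$n > 0) expect_equal(sw$runs$chi2_p, wc$chi2_p)
})

test_that("association_sweep is deterministic", {
  sc <- synthetic_scenario(genome_length = 80000L, n_genes = 50L, seed = 37L)
  ds <- generate_linked_dataset(sc)
  cfg <- sweep_config(window_sizes = c(27L, 47L), category_counts = 3L,
                      score_cutoffs = c(100, 150),
                      offset_range = c(-150L, 0L), window_step = 10L)
  s1 <- association_sweep(ds$genes, ds$mods_a, ds$mods_b,
                          ds$counts_a, ds$counts_b, cfg, genome = ds$genome)
  s2 <- association_sweep(ds$genes, ds$mods_a, ds$mods_b,
                          ds$counts_a, ds$counts_b, cfg, genome = ds$genome)
  expect_identical(s1$runs, s2$runs)
  expect_identical(s1$profile, s2$profile)
})

test_that("seven central nucleotides are credited around the window midpoint", {
  # one significant window must increment exactly 7 offsets
  genes <- make_genes(seq(2000L, by = 2000L, length.out = 40L),
                      seq(2000L, by = 2000L, length.out = 40L) + 999L,
                      rep("+", 40L))
  dirs <- rep(c("up", "down"), 20)
  # concordant modification changes for every gene: strong association
  up_genes <- genes[dirs == "up", ]
  dn_genes <- genes[dirs == "down", ]
  mods_b <- make_mods(up_genes$tsc_position - 50L, "+", score = 150)
  mods_a <- make_mods(dn_genes$tsc_position - 50L, "+", score = 150)
  counts_a <- data.frame(gene_id = genes$gene_id,
                         count = ifelse(dirs == "up", 10, 1000))
  counts_b <- data.frame(gene_id = genes$gene_id,
                         count = ifelse(dirs == "up", 1000, 10))
  cfg <- sweep_config(window_sizes = 27L, category_counts = 2L,
                      score_cutoffs = 100, offset_range = c(-63L, -63L),
                      window_step = 2L, significance_p = 0.01)
  sw <- association_sweep(genes, mods_a, mods_b, counts_a, counts_b, cfg)
  expect_equal(sum(sw$runs$significant), 1L)
  hit <- sw$profile[sw$profile$hit_count > 0, ]
  expect_equal(nrow(hit), 7L)
  mid <- floor(-63 + (27 - 1) / 2)
  expect_setequal(hit$offset, (mid - 3L):(mid + 3L))
})
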