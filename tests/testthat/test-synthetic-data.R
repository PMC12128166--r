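test_that("generate_genome honours composition and determinism", {
  g <- generate_genome(500L, 1.0, 5L)
  expect_true(grepl("^[GC]+$", g$sequence))
  expect_equal(generate_genome(200L, 0.5, 8L)$sequence,
               generate_genome(200L, 0.5, 8L)$sequence)
  expect_false(identical(generate_genome(200L, 0.5, 8L)$sequence,
                         generate_genome(200L, 0.5, 9L)$sequence))
  expect_error(generate_genome(100L, 1.2), "gc")
  # binomial standard error bound on realised GC
  g2 <- generate_genome(100000L, 0.5, 13L)
  gc <- mean(strsplit(g2$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("plant_motifs writes recoverable non-overlapping instances", {
  g <- generate_genome(30000L, 0.5, 21L)
  m <- motif_spec("GaTNNNNNGtGG")
  pl <- plant_motifs(g, m, 25L, seed = 21L)
  expect_equal(nrow(pl$sites), 25L)
  # non-overlap
  s <- pl$sites[order(pl$sites$start), ]
  expect_true(all(diff(s$start) >= m$length))
  found <- scan_motif(pl$genome, m)
  expect_gte(nrow(found$sites), 25L)
  expect_true(all(s$start %in% found$sites$start))
  # n = 0 leaves the genome unchanged
  expect_identical(plant_motifs(g, m, 0L)$genome$sequence, g$sequence)
  tiny <- genome_sequence("c1", strrep("A", 30), circular = FALSE)
  expect_error(plant_motifs(tiny, m, 10L, seed = 1L), "could not place")
})

test_that("methylome generation respects rates and densities", {
  sc <- synthetic_scenario(genome_length = 100000L, n_genes = 20L,
                           noncanonical_density = 0, seed = 2L)
  g <- generate_genome(sc$genome_length, sc$gc, 2L)
  pl <- plant_motifs(g, sc$motifs[[1]], 30L, seed = 2L)
  sites <- scan_motif(pl$genome, sc$motifs[[1]])
  # rate 1, density 0: calls exactly at methylatable positions
  sc1 <- synthetic_scenario(genome_length = 100000L,
                            canonical_methylation_rate = 1,
                            noncanonical_density = 0, seed = 2L)
  m1 <- generate_methylome(pl$genome, sites, sc1, "A")
  expect_setequal(paste(m1$position, m1$strand),
                  paste(sites$positions$position, sites$positions$strand))
  # rate 0, density 0: empty call set
  sc0 <- synthetic_scenario(genome_length = 100000L,
                            canonical_methylation_rate = 0,
                            noncanonical_density = 0, seed = 2L)
  expect_equal(nrow(generate_methylome(pl$genome, sites, sc0, "A")), 0L)
  # density 2 per kbp on 1e5 bp: about 200 non-canonical calls
  sc2 <- synthetic_scenario(genome_length = 100000L,
                            canonical_methylation_rate = 0,
                            noncanonical_density = 2, seed = 2L)
  m2 <- generate_methylome(g, list(), sc2, "A")
  expect_lt(abs(nrow(m2) - 200), 3 * sqrt(200))
})

test_that("methylomes round-trip through the GFF reader", {
  sc <- synthetic_scenario(genome_length = 50000L, n_genes = 20L, seed = 6L)
  g <- generate_genome(sc$genome_length, sc$gc, 6L)
  m <- generate_methylome(g, list(), sc, "A")
  p <- withr::local_tempfile(fileext = ".gff3")
  write_modifications_gff(m, p)
  back <- suppressMessages(read_modifications_gff(p, genome = g))
  expect_equal(back$position, m$position)
  expect_equal(back$strand, m$strand)
  expect_equal(back$base, m$base)
  expect_equal(back$nucmod_score, signif(m$nucmod_score, 6), tolerance = 1e-5)
})

test_that("high-score calls recur across conditions increasingly with score", {
  sc <- synthetic_scenario(genome_length = 400000L, n_genes = 20L, seed = 15L)
  g <- generate_genome(sc$genome_length, sc$gc, 15L)
  ma <- generate_methylome(g, list(), sc, "A")
  mb <- generate_methylome(g, list(), sc, "B")
  kb <- paste(mb$position, mb$strand)
  repeatability <- vapply(c(21, 100, 150), function(cut) {
    ka <- paste(ma$position, ma$strand)[ma$nucmod_score >= cut]
    mean(ka %in% kb)
  }, numeric(1))
  expect_true(all(diff(repeatability) > 0))
})

test_that("generate_linked_dataset plants recoverable structure", {
  sc <- synthetic_scenario(genome_length = 150000L, n_genes = 100L,
                           coupling_strength = 1, seed = 42L)
  ds <- generate_linked_dataset(sc)
  expect_equal(nrow(ds$genes), 100L)
  # genes do not overlap
  expect_true(all(diff(ds$genes$start) > 0))
  expect_true(all(utils::head(ds$genes$end, -1) < utils::tail(ds$genes$start, -1)))
  # every shifted gene is coupled at strength 1 (unless no A/C in window)
  shifted <- ds$truth$shift_dir != 0
  expect_gte(mean(ds$truth$coupled[shifted]), 0.95)
  expect_false(any(ds$truth$coupled[!shifted]))
  # coupled up-genes gained calls in the window under condition B
  co <- ds$truth$coupling_offsets
  i <- which(ds$truth$shift_dir == 1L & ds$truth$coupled)[1]
  g <- ds$genes[i, ]
  rel <- function(m) {
    sel <- m$strand == g$strand
    r <- if (g$strand == "+") m$position[sel] - g$tsc_position
    else g$tsc_position - m$position[sel]
    sum(r >= co[1] & r <= co[2])
  }
  expect_gt(rel(ds$mods_b), rel(ds$mods_a))
})

test_that("ground-truth labels reproduce the contingency table", {
  sc <- synthetic_scenario(genome_length = 150000L, n_genes = 100L,
                           coupling_strength = 1, seed = 51L)
  ds <- generate_linked_dataset(sc)
  pa <- expression_profile(ds$counts_a, ds$genes, k = 3)
  pb <- expression_profile(ds$counts_b, ds$genes, k = 3)
  sh <- category_shifts(pa, pb)
  co <- ds$truth$coupling_offsets
  got <- window_contingency(ds$genes, ds$mods_a, ds$mods_b, sh,
                            offset = co[1], window = co[2] - co[1] + 1L,
                            contig_length = ds$genome$length, circular = TRUE)
  want <- oracle_window_tally(ds$genes, ds$mods_a, ds$mods_b, sh,
                              offset = co[1], window = co[2] - co[1] + 1L)
  expect_equal(c(got$a, got$b, got$c, got$d), unname(want))
  # with full coupling the concordant cells dominate
  expect_gt(got$a + got$d, got$b + got$c)
})

test_that("generators are reproducible and write a complete bundle", {
  sc <- synthetic_scenario(genome_length = 60000L, n_genes = 30L, seed = 4L)
  d1 <- generate_linked_dataset(sc)
  d2 <- generate_linked_dataset(sc)
  expect_identical(d1$genome$sequence, d2$genome$sequence)
  expect_identical(d1$mods_a, d2$mods_a)
  expect_identical(d1$counts_b, d2$counts_b)
  out <- withr::local_tempdir()
  suppressMessages(run_synthesize(d1, out))
  expect_setequal(dir(out),
                  c("genome.fasta", "mods_A.gff3", "mods_B.gff3",
                    "annotation.gff3", "counts_A.tsv", "counts_B.tsv",
                    "truth.json"))
})
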