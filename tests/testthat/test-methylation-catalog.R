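test_that("motif_spec extracts methylatable offsets from lowercase marks", {
  m <- motif_spec("AgGCcT")
  expect_equal(m$iupac, "AGGCCT")
  expect_equal(m$fwd_methyl_offsets, 4L)
  expect_equal(m$rev_methyl_offsets, 1L)
  m2 <- motif_spec("GaTNNNNNGtGG")
  expect_equal(m2$fwd_methyl_offsets, 1L)
  expect_equal(m2$rev_methyl_offsets, 9L)
  expect_error(motif_spec("AXGT"), "IUPAC")
})

test_that("scan_motif finds palindromes once with both-strand positions", {
  g <- genome_sequence("c1", "AAGGCCTT", circular = FALSE)
  s <- scan_motif(g, motif_spec("AgGCcT"))
  expect_equal(nrow(s$sites), 1L)
  expect_equal(s$sites$start, 2L)
  expect_equal(s$sites$end, 7L)
  expect_equal(s$sites$orientation, "+")
  got <- s$positions[order(s$positions$position), ]
  expect_equal(got$position, c(3L, 6L))
  expect_equal(got$strand, c("-", "+"))
  expect_equal(got$base, c("C", "C"))
})

test_that("non-palindromic motifs are found on both strands", {
  g <- genome_sequence("c1", "GATAAAAAGTGG", circular = FALSE)
  s <- scan_motif(g, motif_spec("GaTNNNNNGtGG"))
  expect_equal(s$sites$orientation, "+")
  got <- s$positions[order(s$positions$position), ]
  expect_equal(got$position, c(2L, 10L))
  expect_equal(got$strand, c("+", "-"))
  expect_equal(got$base, c("A", "A"))

  grc <- genome_sequence("c1", "CCACTTTTTATC", circular = FALSE)
  src <- scan_motif(grc, motif_spec("GaTNNNNNGtGG"))
  expect_equal(src$sites$orientation, "-")
  gotrc <- src$positions[order(src$positions$position), ]
  expect_equal(gotrc$position, c(3L, 11L))
  expect_equal(gotrc$strand, c("+", "-"))
  expect_equal(gotrc$base, c("A", "A"))
})

test_that("circular genomes are scanned across the origin", {
  # AGGCCT split across the junction: ...AG | GCCT...
  g <- genome_sequence("c1", paste0("GCCT", strrep("A", 20), "AG"),
                       circular = TRUE)
  s <- scan_motif(g, motif_spec("AgGCcT"))
  expect_equal(nrow(s$sites), 1L)
  expect_equal(s$sites$start, 25L)
  # linear scan must not find it
  g_lin <- genome_sequence("c1", g$sequence, circular = FALSE)
  expect_equal(nrow(scan_motif(g_lin, motif_spec("AgGCcT"))$sites), 0L)
})

test_that("scanning the reverse complement flips orientations", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  g <- genome_sequence("c1", seq, circular = FALSE)
  rc <- genome_sequence("c1",
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))),
    circular = FALSE)
  for (m in canonical_motifs()) {
    s1 <- scan_motif(g, m)
    s2 <- scan_motif(rc, m)
    expect_equal(nrow(s1$sites), nrow(s2$sites))
    expect_equal(sum(s1$sites$orientation == "+"),
                 sum(s2$sites$orientation == "-"))
  }
})

test_that("classification partitions calls exhaustively and disjointly", {
  g <- genome_sequence("c1", "AAGGCCTTGATAAAAAGTGG", circular = FALSE)
  sites <- lapply(canonical_motifs(), function(m) scan_motif(g, m))
  mods <- make_mods(c(6L, 3L, 4L, 10L, 18L), c("+", "-", "+", "+", "-"),
                    base = c("C", "C", "G", "A", "A"))
  cls <- classify_modifications(mods, sites)
  expect_equal(nrow(cls$canonical) + nrow(cls$noncanonical), nrow(mods))
  expect_setequal(cls$canonical$position, c(6L, 3L, 10L, 18L))
  expect_equal(cls$noncanonical$position, 4L)
})

test_that("base mismatches at motif positions demote to non-canonical", {
  g <- genome_sequence("c1", "AAGGCCTT", circular = FALSE)
  sites <- scan_motif(g, motif_spec("AgGCcT"))
  wrong <- make_mods(6L, "+", base = "A")  # motif expects C here
  expect_warning(cls <- classify_modifications(wrong, sites), "demoted")
  expect_equal(nrow(cls$canonical), 0L)
})

test_that("motif_status assigns full, partial and unmethylated states", {
  g <- genome_sequence("c1", "AAGGCCTTAAAGGCCTTTAGGCCTAA", circular = FALSE)
  sites <- scan_motif(g, motif_spec("AgGCcT"))
  expect_equal(sites$sites$start, c(2L, 11L, 19L))
  # site1 (2..7): both positions strong; site2 (11..16): forward only;
  # site3 (19..24): nothing
  mods <- make_mods(c(6L, 3L, 15L), c("+", "-", "+"), base = "C",
                    score = c(150, 140, 99))
  st <- motif_status(sites, mods, score_cutoff = 21)
  expect_equal(unname(st$summary),
               c(1L, 1L, 1L))
  expect_equal(st$status$status[st$status$site_id == sites$sites$site_id[1]],
               "fully_methylated")
  expect_equal(sum(st$summary), nrow(sites$sites))
})

test_that("status counts are monotone in the score cutoff", {
  set.seed(23)
  g <- generate_genome(20000L, 0.5, 23L)
  pl <- plant_motifs(g, motif_spec("AgGCcT"), 15L, seed = 23L)
  sites <- scan_motif(pl$genome, motif_spec("AgGCcT"))
  pos <- sites$positions
  mods <- make_mods(pos$position, pos$strand, base = pos$base,
                    score = runif(nrow(pos), 0, 200))
  cuts <- c(0, 21, 60, 120, 180, 250)
  res <- vapply(cuts, function(cc)
    motif_status(sites, mods, cc)$summary, numeric(3))
  expect_true(all(diff(res["n_fully", ]) <= 0))
  expect_true(all(diff(res["n_unmethylated", ]) >= 0))
})

test_that("planted motifs in motif-free background are recovered exactly", {
  g <- genome_sequence("c1", strrep("A", 5000), circular = TRUE)
  m <- motif_spec("AgGCcT")
  pl <- plant_motifs(g, m, 12L, seed = 9L)
  s <- scan_motif(pl$genome, m)
  expect_equal(nrow(s$sites), 12L)
  expect_setequal(s$sites$start, pl$sites$start)
  # planted canonical calls classify as canonical
  calls <- make_mods(s$positions$position, s$positions$strand,
                     base = s$positions$base)
  cls <- classify_modifications(calls, s)
  expect_equal(nrow(cls$noncanonical), 0L)
})
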