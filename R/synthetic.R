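# Synthetic-data generators: genomes with planted recognition motifs,
# two-condition methylomes with canonical and non-canonical components, and
# two-condition expression with category shifts optionally coupled to
# TSC-proximal modification changes.

#' Describe a synthetic scenario
#'
#' Defaults are a desk-scale stand-in for a single circular bacterial
#' chromosome: 300 kbp at GC 0.55 with 200 non-overlapping genes of mean
#' length 900 bp, both canonical motifs planted, near-complete canonical
#' methylation, ~2 non-canonical calls per kbp with Gaussian score and
#' coverage models centred at 150 and 60, and category-shift coupling in
#' the -80..-20 bp TSC-upstream window.
#'
#' @param genome_length Genome length in bp.
#' @param gc GC fraction.
#' @param n_genes Number of genes.
#' @param gene_length_mean Mean gene length (bp).
#' @param motifs List of [motif_spec()]s to plant.
#' @param motif_plant_n Instances to plant per motif.
#' @param canonical_methylation_rate Per-methylatable-position call
#'   probability.
#' @param noncanonical_density Non-canonical calls per kbp.
#' @param score_model `c(mean, sd)` of non-canonical NucMod scores.
#' @param coverage_model `c(mean, sd)` of read coverage.
#' @param coupling_offsets `c(min, max)` TSC-relative window (bp) receiving
#'   coupled modification changes.
#' @param coupling_strength Probability that a shifted gene receives a
#'   concordant modification change in the coupling window.
#' @param shift_fraction Fraction of genes with a planted expression shift.
#' @param shift_factor Multiplicative expression change of shifted genes.
#' @param n_coupled_calls Calls added per coupled gene.
#' @param call_prob Baseline per-condition call probability of a latent
#'   non-canonical position; each position's propensity modulates it, so
#'   high-scoring calls recur across conditions.
#' @param noncanonical_iid Draw non-canonical positions independently per
#'   condition instead of from a shared latent set (null-testing mode).
#' @param dispersion Negative-binomial size parameter of counts.
#' @param seed Integer seed.
#' @return List of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(genome_length = 300000L, gc = 0.55,
                               n_genes = 200L, gene_length_mean = 900L,
                               motifs = canonical_motifs(),
                               motif_plant_n = 40L,
                               canonical_methylation_rate = 0.97,
                               noncanonical_density = 2,
                               score_model = c(150, 40),
                               coverage_model = c(60, 15),
                               coupling_offsets = c(-80L, -20L),
                               coupling_strength = 0.8,
                               shift_fraction = 0.3,
                               shift_factor = 8,
                               n_coupled_calls = 3L,
                               call_prob = 0.85,
                               noncanonical_iid = FALSE,
                               dispersion = 10,
                               seed = 1L) {
  stopifnot(gc >= 0, gc <= 1, coupling_strength >= 0, coupling_strength <= 1,
            shift_fraction >= 0, shift_fraction <= 1,
            canonical_methylation_rate >= 0, canonical_methylation_rate <= 1,
            call_prob > 0, call_prob <= 1,
            genome_length >= 10 * gene_length_mean)
  structure(as.list(environment()), class = "synthetic_scenario")
}

#' Generate a random circular genome
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length Genome length (bp).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A circular [genome_sequence()] with contig id `"synth_chr"`.
#' @export
generate_genome <- function(length, gc = 0.5, seed = 1L) {
  stopifnot(length >= 1)
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  genome_sequence("synth_chr", paste(bases, collapse = ""), circular = TRUE)
}

.iupac_realize <- function(iupac) {
  letters <- strsplit(iupac, "")[[1]]
  paste(vapply(letters, function(l) {
    opts <- strsplit(Biostrings::IUPAC_CODE_MAP[[l]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

#' Plant literal motif instances into a genome
#'
#' Writes `n` realisations of the motif (degenerate positions randomised)
#' at uniformly chosen non-overlapping positions; background occurrences may
#' add to the scan count. Planted sites never span the origin.
#'
#' @param genome A [genome_sequence()].
#' @param motif A [motif_spec()].
#' @param n Number of instances to plant.
#' @param seed Integer seed.
#' @param occupied Optional `data.frame` of intervals (`start`, `end`)
#'   already taken (e.g. previously planted motifs).
#' @return List with `genome` (modified) and `sites` (ground-truth
#'   `data.frame`: `start`, `end`, `orientation`).
#' @export
plant_motifs <- function(genome, motif, n, seed = 1L, occupied = NULL) {
  stopifnot(inherits(genome, "genome_sequence"), inherits(motif, "motif_spec"))
  if (n == 0L)
    return(list(genome = genome,
                sites = data.frame(start = integer(), end = integer(),
                                   orientation = character())))
  set.seed(seed)
  L <- genome$length
  len <- motif$length
  taken <- if (is.null(occupied)) integer(0) else
    unlist(mapply(seq.int, occupied$start, occupied$end, SIMPLIFY = FALSE))
  starts <- integer(0)
  candidates <- sample.int(L - len + 1L)
  for (s in candidates) {
    if (length(starts) == n) break
    span <- s:(s + len - 1L)
    if (any(span %in% taken)) next
    starts <- c(starts, s)
    taken <- c(taken, span)
  }
  if (length(starts) < n)
    stop("could not place ", n, " non-overlapping motif instances")
  starts <- sort(starts)
  seq <- genome$sequence
  for (s in starts) substr(seq, s, s + len - 1L) <- .iupac_realize(motif$iupac)
  list(genome = genome_sequence(genome$contig_id, seq,
                                circular = genome$circular),
       sites = data.frame(start = starts, end = starts + len - 1L,
                          orientation = "+", stringsAsFactors = FALSE))
}

.trunc_norm <- function(n, mean, sd, lower = 0) {
  pmax(lower, stats::rnorm(n, mean, sd))
}

.tag_seed <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(tag)) * 131L) %% .Machine$integer.max
}

.mods_df <- function(contig, position, strand, base, score, coverage) {
  n <- length(position)
  data.frame(contig_id = rep_len(contig, n), position = as.integer(position),
             strand = strand, base = base,
             mod_type = ifelse(base == "A", "m6A", "m4C"),
             nucmod_score = score,
             coverage = as.integer(round(coverage)),
             ipd_ratio = rep(NA_real_, n), flagged = rep(FALSE, n),
             stringsAsFactors = FALSE)
}

# strand-aware base lookup over a character vector of the genome
.strand_base <- function(chars, pos, strand) {
  b <- chars[pos]
  strand <- rep_len(strand, length(pos))
  ifelse(strand == "-", .complement(b), b)
}

#' Generate one condition's modification calls
#'
#' Canonical calls: each methylatable position of each motif site is called
#' with probability `canonical_methylation_rate`; their scores rise linearly
#' with coverage (the canonical score-coverage cloud). Non-canonical calls:
#' a latent set of modifiable A/C positions fixed per genome (seed only) is
#' sampled per condition with probability `call_prob`, giving the strong
#' cross-condition repeatability of high-scoring calls; in
#' `noncanonical_iid` mode positions are drawn fresh per condition. Scores
#' and coverages come from the scenario's Gaussian models truncated at zero.
#'
#' @param genome A [genome_sequence()].
#' @param sites A `motif_sites` object or list of them (canonical catalog).
#' @param scenario A [synthetic_scenario()].
#' @param condition_tag Condition label (enters the per-condition seed).
#' @param seed Base seed; defaults to the scenario seed.
#' @return Modification `data.frame` in [read_modifications_gff()] schema.
#' @export
generate_methylome <- function(genome, sites, scenario, condition_tag = "A",
                               seed = scenario$seed) {
  chars <- strsplit(genome$sequence, "")[[1]]
  L <- genome$length
  # latent non-canonical positions: same for every condition of this genome.
  # Each carries a propensity z driving both its per-condition call
  # probability and its score, so high-scoring calls recur across
  # conditions (the repeatability pattern of real call sets).
  set.seed(.tag_seed(seed, "latent"))
  mean_p <- stats::integrate(function(z)
    stats::plogis(stats::qlogis(scenario$call_prob) + 1.5 * z) *
      stats::dnorm(z), -Inf, Inf)$value
  n_latent <- round(scenario$noncanonical_density * L / 1000 / mean_p)
  pos_all <- .all_positions(sites)
  canon_key <- character(0)
  if (!is.null(pos_all) && nrow(pos_all))
    canon_key <- paste(pos_all$position, pos_all$strand)
  latent <- data.frame(position = integer(0), strand = character(0),
                       z = numeric(0))
  if (n_latent > 0) {
    cand_pos <- sample.int(L, min(L, n_latent * 3L), replace = FALSE)
    cand_str <- sample(c("+", "-"), length(cand_pos), replace = TRUE)
    b <- .strand_base(chars, cand_pos, cand_str)
    ok <- b %in% c("A", "C") & !(paste(cand_pos, cand_str) %in% canon_key)
    latent <- data.frame(position = cand_pos[ok], strand = cand_str[ok])
    latent <- utils::head(latent, n_latent)
    latent$z <- stats::rnorm(nrow(latent))
  }
  set.seed(.tag_seed(seed, condition_tag))
  out <- list()
  if (!is.null(pos_all) && nrow(pos_all)) {
    called <- stats::runif(nrow(pos_all)) < scenario$canonical_methylation_rate
    cp <- pos_all[called, , drop = FALSE]
    if (nrow(cp)) {
      cov <- .trunc_norm(nrow(cp), scenario$coverage_model[1],
                         scenario$coverage_model[2], lower = 1)
      score <- pmax(21, 2.5 * cov + stats::rnorm(nrow(cp), 0, 15))
      out$canonical <- .mods_df(genome$contig_id, cp$position, cp$strand,
                                cp$base, score, cov)
    }
  }
  if (scenario$noncanonical_iid) {
    n_calls <- stats::rpois(1, scenario$noncanonical_density * L / 1000)
    cand_pos <- sample.int(L, min(L, n_calls * 3L))
    cand_str <- sample(c("+", "-"), length(cand_pos), replace = TRUE)
    b <- .strand_base(chars, cand_pos, cand_str)
    ok <- b %in% c("A", "C") & !(paste(cand_pos, cand_str) %in% canon_key)
    nc <- utils::head(data.frame(position = cand_pos[ok],
                                 strand = cand_str[ok]), n_calls)
    nc$z <- stats::rnorm(nrow(nc))
  } else {
    p_call <- stats::plogis(stats::qlogis(scenario$call_prob) +
                              1.5 * latent$z)
    keep <- stats::runif(nrow(latent)) < p_call
    nc <- latent[keep, , drop = FALSE]
  }
  if (nrow(nc)) {
    cov <- .trunc_norm(nrow(nc), scenario$coverage_model[1],
                       scenario$coverage_model[2], lower = 1)
    # score = shared propensity component + per-condition noise
    score <- pmax(0, scenario$score_model[1] + scenario$score_model[2] *
                    (0.7 * nc$z + 0.72 * stats::rnorm(nrow(nc))))
    out$noncanonical <- .mods_df(genome$contig_id, nc$position, nc$strand,
                                 .strand_base(chars, nc$position, nc$strand),
                                 score, cov)
  }
  mods <- do.call(rbind, out)
  if (is.null(mods)) mods <- .mods_df(character(0), integer(0), character(0),
                                      character(0), numeric(0), numeric(0))
  mods <- mods[order(mods$position, mods$strand), , drop = FALSE]
  rownames(mods) <- NULL
  mods
}

# place n non-overlapping genes with intergenic gaps wide enough for
# upstream windows; strands alternate at random
.place_genes <- function(scenario) {
  n <- scenario$n_genes
  lens <- pmax(300L, as.integer(round(stats::rnorm(
    n, scenario$gene_length_mean, scenario$gene_length_mean / 4))))
  gaps <- as.integer(round(stats::runif(n, 380, 520)))
  need <- sum(lens) + sum(gaps)
  if (need > scenario$genome_length)
    stop("genome too short for ", n, " genes (need ~", need, " bp)")
  starts <- integer(n)
  pos <- gaps[1]
  for (i in seq_len(n)) {
    starts[i] <- pos + 1L
    pos <- pos + lens[i] + if (i < n) gaps[i + 1L] else 0L
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ends <- starts + lens - 1L
  data.frame(gene_id = sprintf("gene_%04d", seq_len(n)),
             contig_id = "synth_chr", start = starts, end = ends,
             strand = strand,
             tsc_position = ifelse(strand == "+", starts, ends),
             length = lens, stringsAsFactors = FALSE)
}

#' Generate a complete two-condition dataset with known ground truth
#'
#' Builds a genome with planted canonical motifs, non-overlapping genes on
#' both strands, negative-binomial expression counts where a
#' `shift_fraction` of genes shifts expression category between conditions,
#' and per-condition methylomes. For each shifted gene, with probability
#' `coupling_strength`, a concordant modification-count change is written
#' into the coupling window on the gene's strand (calls added under the
#' condition with higher expression for up-shifts, under the other for
#' down-shifts). The coupling acts on the modification calls only; gene
#' coordinates are never moved.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `genome`, `genes`, `mods_a`, `mods_b`, `counts_a`,
#'   `counts_b`, `motif_sites` (scanned catalog), and `truth` (per-gene
#'   planted shift direction and coupling flag, plus the planted window).
#' @export
generate_linked_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  seed <- scenario$seed
  genome <- generate_genome(scenario$genome_length, scenario$gc, seed)
  planted <- list()
  occupied <- NULL
  for (mi in seq_along(scenario$motifs)) {
    m <- scenario$motifs[[mi]]
    pl <- plant_motifs(genome, m, scenario$motif_plant_n,
                       seed = .tag_seed(seed, paste0("plant", mi)),
                       occupied = occupied)
    genome <- pl$genome
    planted[[m$name]] <- pl$sites
    occupied <- rbind(occupied, pl$sites[c("start", "end")])
  }
  sites <- lapply(scenario$motifs, function(m) scan_motif(genome, m))
  set.seed(.tag_seed(seed, "genes"))
  genes <- .place_genes(scenario)
  n <- nrow(genes)
  mu <- stats::rlnorm(n, log(200), 1)
  counts_a <- stats::rnbinom(n, mu = mu, size = scenario$dispersion)
  shift_dir <- integer(n)
  n_shift <- round(n * scenario$shift_fraction)
  if (n_shift > 0) {
    idx <- sample.int(n, n_shift)
    shift_dir[idx] <- sample(c(-1L, 1L), n_shift, replace = TRUE)
  }
  mu_b <- mu * scenario$shift_factor^shift_dir
  counts_b <- stats::rnbinom(n, mu = mu_b, size = scenario$dispersion)
  mods_a <- generate_methylome(genome, sites, scenario, "A", seed)
  mods_b <- generate_methylome(genome, sites, scenario, "B", seed)
  # coupled modification changes in the planted TSC-relative window
  set.seed(.tag_seed(seed, "coupling"))
  chars <- strsplit(genome$sequence, "")[[1]]
  coupled <- rep(FALSE, n)
  co <- scenario$coupling_offsets
  extra <- list(A = list(), B = list())
  for (i in seq_len(n)) {
    if (shift_dir[i] == 0L) next
    if (stats::runif(1) > scenario$coupling_strength) next
    g <- genes[i, ]
    rel <- co[1]:co[2]
    pos <- if (g$strand == "+") g$tsc_position + rel else g$tsc_position - rel
    pos <- .wrap_pos(pos, genome$length)
    b <- .strand_base(chars, pos, g$strand)
    pos <- pos[b %in% c("A", "C")]
    if (length(pos) == 0L) next
    take <- sample(pos, min(scenario$n_coupled_calls, length(pos)))
    cov <- .trunc_norm(length(take), scenario$coverage_model[1],
                       scenario$coverage_model[2], lower = 1)
    score <- .trunc_norm(length(take), scenario$score_model[1],
                         scenario$score_model[2])
    calls <- .mods_df(genome$contig_id, take, g$strand,
                      .strand_base(chars, take, g$strand), score, cov)
    side <- if (shift_dir[i] > 0L) "B" else "A"
    extra[[side]][[length(extra[[side]]) + 1L]] <- calls
    coupled[i] <- TRUE
  }
  if (length(extra$A)) mods_a <- rbind(mods_a, do.call(rbind, extra$A))
  if (length(extra$B)) mods_b <- rbind(mods_b, do.call(rbind, extra$B))
  mods_a <- mods_a[order(mods_a$position, mods_a$strand), ]
  mods_b <- mods_b[order(mods_b$position, mods_b$strand), ]
  rownames(mods_a) <- rownames(mods_b) <- NULL
  list(genome = genome, genes = genes,
       mods_a = mods_a, mods_b = mods_b,
       counts_a = data.frame(gene_id = genes$gene_id, count = counts_a,
                             stringsAsFactors = FALSE),
       counts_b = data.frame(gene_id = genes$gene_id, count = counts_b,
                             stringsAsFactors = FALSE),
       motif_sites = sites,
       truth = list(gene_id = genes$gene_id, shift_dir = shift_dir,
                    coupled = coupled, coupling_offsets = co,
                    planted_motif_sites = planted),
       scenario = scenario)
}
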