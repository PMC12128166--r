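# TSC-relative sliding-window contingency analysis: chi-squared association,
# raw and normalised linkage disequilibrium (Lewontin D'), BH FDR control,
# binomial robustness and the parameter-grid sweep.

# Vectorised 2x2 machinery shared by the scalar API and the sweep.
.margins <- function(a, b, c, d) {
  n <- a + b + c + d
  list(n = n, r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d)
}

.ld_vec <- function(a, b, c, d) {
  m <- .margins(a, b, c, d)
  n <- m$n
  pr <- m$r1 / n
  pc <- m$c1 / n
  D <- a / n - pr * pc
  dmax <- ifelse(D > 0,
                 pmin(pr * (1 - pc), (1 - pr) * pc),
                 pmin(pr * pc, (1 - pr) * (1 - pc)))
  defined <- m$r1 > 0 & m$r2 > 0 & m$c1 > 0 & m$c2 > 0
  ldn <- ifelse(D == 0, 0, D / dmax)
  ldn <- pmin(1, pmax(-1, ldn))  # guard float spill past the bounds
  ldn[!defined] <- NA_real_
  list(ld_raw = D, ld_norm = ldn, defined = defined)
}

.chi2_vec <- function(a, b, c, d, correction = TRUE) {
  m <- .margins(a, b, c, d)
  zero_margin <- m$r1 == 0 | m$r2 == 0 | m$c1 == 0 | m$c2 == 0
  dd <- abs(a * d - b * c)
  if (correction) dd <- pmax(0, dd - m$n / 2)
  denom <- m$r1 * m$r2 * m$c1 * m$c2
  stat <- ifelse(zero_margin, 0, m$n * dd^2 / denom)
  p <- ifelse(zero_margin, 1,
              stats::pchisq(stat, df = 1, lower.tail = FALSE))
  list(p = p, statistic = stat, flagged = zero_margin)
}

#' Raw and normalised linkage disequilibrium of a 2x2 table
#'
#' The raw LD is the first-cell frequency minus its expectation under
#' independence, `a/n - ((a+b)/n) * ((a+c)/n)`. The normalised LD' divides
#' by the maximum attainable |LD| given the margins (Lewontin-style):
#' `min(p_row (1-p_col), (1-p_row) p_col)` for positive LD and
#' `min(p_row p_col, (1-p_row)(1-p_col))` for negative LD. LD' is undefined
#' (returned as `NA` with `defined = FALSE`) when any margin is zero.
#'
#' @param a,b,c,d Cell counts of the table `[[a, b], [c, d]]`.
#' @return List with `ld_raw`, `ld_norm`, `defined`.
#' @export
ld_prime <- function(a, b, c, d) {
  stopifnot(length(a) == 1L, a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b + c + d < 1) stop("all-zero contingency table")
  .ld_vec(a, b, c, d)
}

#' Chi-squared independence p-value for a 2x2 table
#'
#' One degree of freedom; Yates continuity correction applied when
#' `correction` is `TRUE` (the default, matching the behaviour of standard
#' contingency routines on 2x2 tables). A table with a zero margin carries
#' no information and is returned as p = 1 with the `flagged` attribute set.
#'
#' @inheritParams ld_prime
#' @param correction Apply the continuity correction?
#' @return The p-value, with attributes `statistic` and `flagged`.
#' @export
contingency_p <- function(a, b, c, d, correction = TRUE) {
  if (a + b + c + d < 1) stop("empty contingency table")
  r <- .chi2_vec(a, b, c, d, correction)
  structure(r$p, statistic = r$statistic, flagged = r$flagged)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Vector of p-values in `[0, 1]`.
#' @param alpha FDR level for the rejection flags (default 0.05).
#' @return List with `adjusted` (monotone step-up adjusted p-values, capped
#'   at 1, in input order) and `reject` (`adjusted <= alpha`).
#' @export
bh_adjust <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  m <- length(pvalues)
  if (m == 0L) return(list(adjusted = numeric(0), reject = logical(0)))
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  adjusted <- pmin(1, cummin(pvalues[o] * m / (m:1)))[ro]
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Exact two-sided binomial test
#'
#' Point-probability method: the p-value sums `P(X = i)` over all outcomes
#' no more likely than the observed one. Used as the robustness check on the
#' count of genes whose modification change and expression change are
#' concordant (`a + d` of `n`).
#'
#' @param k Observed successes.
#' @param n Number of trials (>= 1).
#' @param p0 Null success probability (default 0.5).
#' @return The two-sided p-value.
#' @export
binomial_direction_test <- function(k, n, p0 = 0.5) {
  stopifnot(n >= 1, k >= 0, k <= n, p0 > 0, p0 < 1)
  dens <- stats::dbinom(0:n, n, p0)
  min(1, sum(dens[dens <= dens[k + 1] * (1 + 1e-7)]))
}

# Signed TSC-relative coordinate of positions for one gene; coordinates
# increase in the gene's reading direction. Circular contigs use the minimal
# signed difference.
.relative_position <- function(pos, tsc, strand, contig_length = NULL,
                               circular = FALSE) {
  d <- if (strand == "+") pos - tsc else tsc - pos
  if (circular && !is.null(contig_length)) {
    L <- contig_length
    d <- ((d %% L) + L) %% L
    d <- ifelse(d > L / 2, d - L, d)
  }
  d
}

#' Contingency table for one TSC-relative window
#'
#' For each gene the window spans `[offset, offset + window - 1]` in
#' strand-aware coordinates relative to its transcriptional start codon
#' (negative offsets upstream). Modification calls are counted on the gene's
#' strand only, in both conditions. A gene contributes only when its window
#' counts differ strictly between conditions and its expression category
#' shifted; the cells are `a` (more modifications, expression up), `b`
#' (fewer, up), `c` (more, down), `d` (fewer, down).
#'
#' @param genes Gene models.
#' @param mods_a,mods_b Modification calls under the two conditions.
#' @param shifts Category shifts from [category_shifts()].
#' @param offset Window start relative to the TSC (bp; negative upstream).
#' @param window Window size in bp.
#' @param score_cutoff Calls below this score are ignored (default 0).
#' @param contig_length,circular Circular-genome geometry for genes close to
#'   the origin; linear arithmetic when `contig_length` is `NULL`.
#' @param correction Continuity correction for the chi-squared p.
#' @return One-row `data.frame` with the window, cells, `n`, `chi2_p`,
#'   `ld_raw`, `ld_norm`, `ld_defined`, `n_genes_eligible`, `flagged`.
#' @export
window_contingency <- function(genes, mods_a, mods_b, shifts, offset, window,
                               score_cutoff = 0, contig_length = NULL,
                               circular = FALSE, correction = TRUE) {
  stopifnot(window >= 1)
  dir <- shifts$direction[match(genes$gene_id, shifts$gene_id)]
  count_in <- function(mods, g) {
    sel <- mods$contig_id == g$contig_id & mods$strand == g$strand &
      mods$nucmod_score >= score_cutoff
    if (!any(sel)) return(0L)
    r <- .relative_position(mods$position[sel], g$tsc_position, g$strand,
                            contig_length, circular)
    sum(r >= offset & r <= offset + window - 1L)
  }
  cells <- c(a = 0L, b = 0L, c = 0L, d = 0L)
  for (i in seq_len(nrow(genes))) {
    if (is.na(dir[i]) || dir[i] == "none") next
    g <- genes[i, ]
    delta <- count_in(mods_b, g) - count_in(mods_a, g)
    if (delta == 0L) next
    cell <- if (dir[i] == "up") {
      if (delta > 0L) "a" else "b"
    } else {
      if (delta > 0L) "c" else "d"
    }
    cells[cell] <- cells[cell] + 1L
  }
  n <- sum(cells)
  if (n == 0L) {
    return(data.frame(offset_start = offset, offset_end = offset + window - 1L,
                      window = window, a = 0L, b = 0L, c = 0L, d = 0L, n = 0L,
                      chi2_p = NA_real_, ld_raw = NA_real_,
                      ld_norm = NA_real_, ld_defined = FALSE,
                      n_genes_eligible = 0L, flagged = TRUE))
  }
  chi <- .chi2_vec(cells["a"], cells["b"], cells["c"], cells["d"], correction)
  ld <- .ld_vec(cells["a"], cells["b"], cells["c"], cells["d"])
  data.frame(offset_start = offset, offset_end = offset + window - 1L,
             window = window,
             a = cells[["a"]], b = cells[["b"]], c = cells[["c"]],
             d = cells[["d"]], n = n,
             chi2_p = chi$p, ld_raw = ld$ld_raw, ld_norm = ld$ld_norm,
             ld_defined = ld$defined, n_genes_eligible = n,
             flagged = chi$flagged)
}

#' Sweep configuration
#'
#' @param window_sizes Window sizes in bp (each >= 7, so the seven central
#'   nucleotides exist).
#' @param window_step Offset step along the TSC-relative axis (bp).
#' @param offset_range Length-2 vector: smallest and largest window start
#'   offset relative to the TSC (negative upstream).
#' @param category_counts Numbers of expression categories to sweep.
#' @param score_cutoffs NucMod score cutoffs to sweep.
#' @param significance_p Per-window significance threshold (default 0.006).
#' @param fdr_alpha BH FDR level (default 0.05).
#' @param correction Continuity correction for chi-squared (default `TRUE`).
#' @return List of class `sweep_config`.
#' @export
sweep_config <- function(window_sizes = seq(27L, 90L, by = 5L),
                         window_step = 2L,
                         offset_range = c(-350L, 100L),
                         category_counts = 3:6,
                         score_cutoffs = seq(100, 200, by = 25),
                         significance_p = 0.006,
                         fdr_alpha = 0.05,
                         correction = TRUE) {
  stopifnot(length(window_sizes) > 0, all(window_sizes >= 7),
            length(category_counts) > 0, length(score_cutoffs) > 0,
            length(offset_range) == 2, offset_range[1] <= offset_range[2],
            window_step >= 1)
  structure(list(window_sizes = as.integer(window_sizes),
                 window_step = as.integer(window_step),
                 offset_range = as.integer(offset_range),
                 category_counts = as.integer(category_counts),
                 score_cutoffs = as.numeric(score_cutoffs),
                 significance_p = significance_p,
                 fdr_alpha = fdr_alpha,
                 correction = isTRUE(correction)),
            class = "sweep_config")
}

#' Named sweep presets
#'
#' `"main"`: windows 27-90 bp by 5, 3-6 expression categories, score
#' cutoffs 100-200 by 25 (the deep-scan grid). `"alt"`: windows 20-50 bp by
#' 5, 4-8 categories, cutoffs 20-50 by 5 (the shallow variant).
#'
#' @param name Preset name.
#' @return A [sweep_config()].
#' @export
sweep_preset <- function(name = c("main", "alt")) {
  name <- match.arg(name)
  switch(name,
         main = sweep_config(),
         alt = sweep_config(window_sizes = seq(20L, 50L, by = 5L),
                            category_counts = 4:8,
                            score_cutoffs = seq(20, 50, by = 5)))
}

# counts of per-gene modification calls at every TSC-relative coordinate in
# [rmin, rmax]; returns a genes x span cumulative-count matrix padded with a
# leading zero column so window counts are CS[, hi + 1] - CS[, lo]
.relative_cumcounts <- function(genes, mods, rmin, rmax, score_cutoff,
                                contig_length, circular) {
  span <- rmax - rmin + 1L
  M <- matrix(0L, nrow = nrow(genes), ncol = span)
  keep <- mods$nucmod_score >= score_cutoff
  mods <- mods[keep, , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    sel <- mods$contig_id == g$contig_id & mods$strand == g$strand
    if (!any(sel)) next
    r <- .relative_position(mods$position[sel], g$tsc_position, g$strand,
                            contig_length, circular)
    r <- r[r >= rmin & r <= rmax]
    if (length(r)) M[i, ] <- tabulate(r - rmin + 1L, nbins = span)
  }
  cbind(0L, t(apply(M, 1L, cumsum)))
}

#' Full parameter-grid association sweep
#'
#' For every grid point (window size x category count x score cutoff) the
#' TSC-relative axis is scanned with [window_contingency] semantics; BH
#' adjustment is applied across the windows of each grid point; whenever a
#' window's chi-squared p-value is at or below `significance_p` (and its
#' LD' is defined), the seven central nucleotides of the window
#' (`floor(mid) - 3 ... floor(mid) + 3`, `mid = offset + (window - 1)/2`)
#' are credited with a hit and the window's LD' accumulated. Run the sweep
#' separately for adenine and cytosine calls by subsetting `mods_a` /
#' `mods_b` on `base` beforehand.
#'
#' @param genes Gene models.
#' @param mods_a,mods_b Modification calls for the two conditions
#'   (unfiltered; cutoffs come from the grid).
#' @param counts_a,counts_b Per-condition count tables (`gene_id`, `count`).
#' @param config A [sweep_config()].
#' @param genome Optional [genome_sequence()] for circular coordinate
#'   arithmetic.
#' @param metric Expression metric used for categorisation.
#' @return List of class `sweep_result`: `profile` (per TSC-relative
#'   nucleotide: `offset`, `hit_count`, `mean_ld`, `n_positive`,
#'   `n_negative`, `ld_sign_profile`), `runs` (the complete per-window log)
#'   and `config`.
#' @export
association_sweep <- function(genes, mods_a, mods_b, counts_a, counts_b,
                              config = sweep_preset("main"), genome = NULL,
                              metric = "rpkm") {
  stopifnot(inherits(config, "sweep_config"))
  if (length(config$window_sizes) == 0L) stop("empty sweep grid")
  L <- if (!is.null(genome)) genome$length else NULL
  circ <- if (!is.null(genome)) genome$circular else FALSE
  off <- config$offset_range
  offsets <- seq.int(off[1], off[2], by = config$window_step)
  maxw <- max(config$window_sizes)
  rmin <- off[1]
  rmax <- off[2] + maxw - 1L
  # per-k shift directions, aligned to the gene table
  dirs <- lapply(config$category_counts, function(k) {
    pa <- expression_profile(counts_a, genes, k = k, metric = metric)
    pb <- expression_profile(counts_b, genes, k = k, metric = metric)
    sh <- category_shifts(pa, pb)
    d <- sh$direction[match(genes$gene_id, sh$gene_id)]
    ifelse(is.na(d), 0L, ifelse(d == "up", 1L, ifelse(d == "down", -1L, 0L)))
  })
  names(dirs) <- as.character(config$category_counts)
  # per-cutoff cumulative relative-position counts
  cums <- lapply(config$score_cutoffs, function(cut) list(
    A = .relative_cumcounts(genes, mods_a, rmin, rmax, cut, L, circ),
    B = .relative_cumcounts(genes, mods_b, rmin, rmax, cut, L, circ)))
  names(cums) <- as.character(config$score_cutoffs)

  prof_min <- off[1] + (min(config$window_sizes) - 1L) %/% 2L - 3L
  prof_max <- off[2] + (maxw - 1L) %/% 2L + 3L
  prof_offsets <- prof_min:prof_max
  hits <- integer(length(prof_offsets))
  ld_sum <- numeric(length(prof_offsets))
  n_pos <- integer(length(prof_offsets))
  n_neg <- integer(length(prof_offsets))
  runs <- vector("list", 0L)

  for (w in config$window_sizes) {
    lo_idx <- offsets - rmin + 1L
    hi_idx <- offsets + w - 1L - rmin + 2L
    for (ki in seq_along(config$category_counts)) {
      dir <- dirs[[ki]]
      up <- dir == 1L
      dn <- dir == -1L
      for (ci in seq_along(config$score_cutoffs)) {
        CA <- cums[[ci]]$A
        CB <- cums[[ci]]$B
        countA <- CA[, hi_idx, drop = FALSE] - CA[, lo_idx, drop = FALSE]
        countB <- CB[, hi_idx, drop = FALSE] - CB[, lo_idx, drop = FALSE]
        delta <- countB - countA
        a <- colSums(delta > 0L & up)
        b <- colSums(delta < 0L & up)
        cc <- colSums(delta > 0L & dn)
        d <- colSums(delta < 0L & dn)
        n <- a + b + cc + d
        chi <- .chi2_vec(a, b, cc, d, config$correction)
        ld <- .ld_vec(a, b, cc, d)
        p <- ifelse(n == 0L, NA_real_, chi$p)
        nonempty <- n > 0L
        adj <- rep(NA_real_, length(p))
        rej <- rep(FALSE, length(p))
        if (any(nonempty)) {
          bh <- bh_adjust(p[nonempty], config$fdr_alpha)
          adj[nonempty] <- bh$adjusted
          rej[nonempty] <- bh$reject
        }
        sig <- nonempty & !is.na(p) & p <= config$significance_p & ld$defined
        runs[[length(runs) + 1L]] <- data.frame(
          window = w, k = config$category_counts[ki],
          score_cutoff = config$score_cutoffs[ci], offset = offsets,
          a = a, b = b, c = cc, d = d, n = n,
          chi2_p = p, adjusted_p = adj, bh_reject = rej,
          ld_raw = ifelse(n == 0L, NA_real_, ld$ld_raw),
          ld_norm = ld$ld_norm, significant = sig)
        if (any(sig)) {
          mids <- floor(offsets[sig] + (w - 1) / 2)
          ldn <- ld$ld_norm[sig]
          for (j in seq_along(mids)) {
            span <- (mids[j] - 3L):(mids[j] + 3L)
            idx <- span - prof_min + 1L
            idx <- idx[idx >= 1L & idx <= length(prof_offsets)]
            hits[idx] <- hits[idx] + 1L
            ld_sum[idx] <- ld_sum[idx] + ldn[j]
            if (ldn[j] > 0) n_pos[idx] <- n_pos[idx] + 1L
            if (ldn[j] < 0) n_neg[idx] <- n_neg[idx] + 1L
          }
        }
      }
    }
  }
  profile <- data.frame(
    offset = prof_offsets, hit_count = hits,
    mean_ld = ifelse(hits > 0L, ld_sum / hits, NA_real_),
    n_positive = n_pos, n_negative = n_neg,
    ld_sign_profile = ifelse(hits == 0L, NA_character_,
                             ifelse(n_neg == 0L, "positive",
                                    ifelse(n_pos == 0L, "negative", "mixed"))),
    stringsAsFactors = FALSE)
  structure(list(profile = profile, runs = do.call(rbind, runs),
                 config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  sig <- sum(x$runs$significant, na.rm = TRUE)
  cat(sprintf(
    "<sweep_result> %d grid windows evaluated, %d significant; hit profile over offsets %d..%d (max hit_count %d)\n",
    nrow(x$runs), sig, min(x$profile$offset), max(x$profile$offset),
    max(x$profile$hit_count)))
  invisible(x)
}
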