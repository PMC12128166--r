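# Chromosome-wide sliding-window profiles, bootstrap Spearman correlations
# and region-bias Z statistics.

#' Sliding-window GC / modification profile of a chromosome
#'
#' Windows are placed every `step` bp; on circular genomes the final windows
#' wrap across the origin so the whole chromosome is tiled. Modification
#' calls are counted by position with strands pooled.
#'
#' @param genome A [genome_sequence()].
#' @param mods Modification calls (may be empty).
#' @param window Window size in bp (default 8000).
#' @param step Step size in bp (default 2000).
#' @return `data.frame` with `contig_id`, `start`, `end`, `gc_content`,
#'   `gc_skew`, `skew_defined`, `mod_count`. `end` may exceed the contig
#'   length for origin-wrapping windows.
#' @export
window_profile <- function(genome, mods, window = 8000L, step = 2000L) {
  stopifnot(inherits(genome, "genome_sequence"))
  L <- genome$length
  if (window > L) stop("window exceeds genome length")
  if (step < 1L) stop("step must be >= 1")
  chars <- strsplit(genome$sequence, "")[[1]]
  is_g <- as.integer(chars == "G")
  is_c <- as.integer(chars == "C")
  cnt <- integer(L)
  if (!is.null(mods) && nrow(mods)) {
    sel <- mods$contig_id == genome$contig_id
    cnt <- tabulate(mods$position[sel], nbins = L)
  }
  if (genome$circular) {
    starts <- seq.int(1L, L, by = step)
    is_g <- c(is_g, is_g[seq_len(window - 1L)])
    is_c <- c(is_c, is_c[seq_len(window - 1L)])
    cnt <- c(cnt, cnt[seq_len(window - 1L)])
  } else {
    starts <- seq.int(1L, max(1L, L - window + 1L), by = step)
  }
  cg <- c(0L, cumsum(is_g))
  cc <- c(0L, cumsum(is_c))
  cm <- c(0, cumsum(cnt))
  ends <- starts + window - 1L
  g <- cg[ends + 1L] - cg[starts]
  c_ <- cc[ends + 1L] - cc[starts]
  m <- cm[ends + 1L] - cm[starts]
  skew_defined <- (g + c_) > 0L
  data.frame(
    contig_id = genome$contig_id, start = starts, end = ends,
    gc_content = (g + c_) / window,
    gc_skew = ifelse(skew_defined, (g - c_) / (g + c_), 0),
    skew_defined = skew_defined,
    mod_count = as.integer(m),
    stringsAsFactors = FALSE)
}

#' Spearman correlation with percentile-bootstrap confidence interval
#'
#' Pairs are resampled with replacement `n_boot` times; the CI is the
#' `(alpha/2, 1 - alpha/2)` percentile interval of the bootstrap Spearman
#' coefficients. The correlation is called significant when both CI
#' boundaries are on the same side of zero.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param alpha CI level complement (default 0.05 for a 95% CI).
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `correlation_report` with `rho`, `ci_low`,
#'   `ci_high`, `n_boot`, `alpha`, `significant`, `flagged`.
#' @export
spearman_bootstrap <- function(x, y, n_boot = 1000L, alpha = 0.05,
                               seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  if (!is.null(seed)) set.seed(seed)
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    rep <- list(rho = 0, ci_low = NA_real_, ci_high = NA_real_,
                n_boot = as.integer(n_boot), alpha = alpha,
                significant = FALSE, flagged = TRUE)
    return(structure(rep, class = "correlation_report"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  boots <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, n, replace = TRUE)
    xs <- x[idx]; ys <- y[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(rank(xs), rank(ys))
  }, numeric(1))
  ci <- stats::quantile(boots, c(alpha / 2, 1 - alpha / 2),
                        na.rm = TRUE, names = FALSE, type = 7)
  structure(list(rho = rho, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), alpha = alpha,
                 significant = (ci[1] > 0 && ci[2] > 0) ||
                   (ci[1] < 0 && ci[2] < 0),
                 flagged = FALSE),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, %d%% CI [%.3f, %.3f] (%s)\n",
              x$rho, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# split an interval that may run off a circular contig into wrapped pieces,
# or truncate it on a linear contig
.normalize_interval <- function(start, end, L, circular) {
  if (circular) {
    start <- .wrap_pos(start, L)
    end2 <- start + (end - start)
    if (end2 <= L) return(data.frame(start = start, end = end2))
    return(data.frame(start = c(start, 1L), end = c(L, end2 - L)))
  }
  data.frame(start = max(1L, start), end = min(L, end))
}

.ranges_of <- function(df) IRanges::IRanges(df$start, df$end)

#' Partition the chromosome into analysis region classes
#'
#' Builds two independent partitions of the chromosome: (i) `mge` (mobile
#' genetic elements / genomic islands, from the BED input) versus `core`;
#' (ii) `tsc_upstream` (the `upstream_len` bases 5' of each gene's start
#' codon on the gene's strand, projected to chromosome coordinates, taking
#' precedence), then `coding` (gene bodies not already upstream), then
#' `noncoding` (the remainder). Upstream regions wrap across the origin on
#' circular contigs and are truncated on linear ones.
#'
#' @param genes Gene models (see [read_annotation_gff()]).
#' @param genome A [genome_sequence()].
#' @param islands Optional island intervals (`contig_id`, `start`, `end`,
#'   1-based inclusive).
#' @param upstream_len Length of the TSC-upstream window (default 120 bp).
#' @return `data.frame` with `partition` (`"mge_core"` or `"functional"`),
#'   `label`, `contig_id`, `start`, `end`.
#' @export
build_region_sets <- function(genes, genome, islands = NULL,
                              upstream_len = 120L) {
  L <- genome$length
  cid <- genome$contig_id
  genes <- genes[genes$contig_id == cid, , drop = FALSE]
  up <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+")
      .normalize_interval(g$tsc_position - upstream_len,
                          g$tsc_position - 1L, L, genome$circular)
    else
      .normalize_interval(g$tsc_position + 1L,
                          g$tsc_position + upstream_len, L, genome$circular)
  }))
  whole <- IRanges::IRanges(1L, L)
  up_ir <- if (is.null(up)) IRanges::IRanges() else
    IRanges::reduce(.ranges_of(up))
  cds_ir <- IRanges::reduce(IRanges::IRanges(genes$start, genes$end))
  coding_ir <- IRanges::setdiff(cds_ir, up_ir)
  noncoding_ir <- IRanges::setdiff(IRanges::setdiff(whole, up_ir), coding_ir)
  mge_ir <- if (is.null(islands) || nrow(islands) == 0L) IRanges::IRanges()
  else IRanges::reduce(.ranges_of(islands[islands$contig_id == cid, ]))
  core_ir <- IRanges::setdiff(whole, mge_ir)
  as_df <- function(ir, partition, label) {
    if (length(ir) == 0L)
      return(data.frame(partition = character(), label = character(),
                        contig_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    data.frame(partition = partition, label = label, contig_id = cid,
               start = BiocGenerics::start(ir), end = BiocGenerics::end(ir),
               stringsAsFactors = FALSE)
  }
  rbind(as_df(up_ir, "functional", "tsc_upstream"),
        as_df(coding_ir, "functional", "coding"),
        as_df(noncoding_ir, "functional", "noncoding"),
        as_df(mge_ir, "mge_core", "mge"),
        as_df(core_ir, "mge_core", "core"))
}

#' Region-bias Z statistics for modified-base distribution
#'
#' For each region label the expected count is the total number of calls
#' scaled by the label's share of the genome; the bias statistic is
#' `Z = (F_obs - F_exp) / sqrt(F_exp + 1)` and its p-value the standard
#' normal survival function at `|Z|`. Calls are assigned by position with
#' strands pooled; within each partition every call lands in exactly one
#' label.
#'
#' @param mods Modification calls.
#' @param regions Region table from [build_region_sets()].
#' @param genome A [genome_sequence()].
#' @return `data.frame` with `partition`, `label`, `territory_bp`, `f_obs`,
#'   `f_exp`, `z`, `p`.
#' @export
region_bias <- function(mods, regions, genome) {
  cid <- genome$contig_id
  mods <- mods[mods$contig_id == cid, , drop = FALSE]
  total <- nrow(mods)
  mod_ir <- IRanges::IRanges(mods$position, width = 1L)
  out <- list()
  for (part in unique(regions$partition)) {
    reg <- regions[regions$partition == part, , drop = FALSE]
    for (lab in unique(reg$label)) {
      r <- reg[reg$label == lab, , drop = FALSE]
      ir <- IRanges::reduce(.ranges_of(r))
      territory <- sum(IRanges::width(ir))
      f_obs <- sum(IRanges::overlapsAny(mod_ir, ir))
      f_exp <- total * territory / genome$length
      z <- (f_obs - f_exp) / sqrt(f_exp + 1)
      out[[length(out) + 1L]] <- data.frame(
        partition = part, label = lab, territory_bp = territory,
        f_obs = f_obs, f_exp = f_exp, z = z,
        p = stats::pnorm(abs(z), lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
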