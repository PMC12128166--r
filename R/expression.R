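# Expression metrics: RPKM, TPM, equal-size expression categories and
# per-gene category shifts between two growth conditions.

#' Reads per kilobase per million mapped reads
#'
#' `rpkm_i = counts_i * 1e9 / total_mapped / length_i`.
#'
#' @param counts Per-gene non-negative read counts.
#' @param gene_lengths Per-gene lengths in bp (positive).
#' @param total_mapped Library size; defaults to `sum(counts)`.
#' @return Numeric vector of RPKM values.
#' @export
compute_rpkm <- function(counts, gene_lengths, total_mapped = sum(counts)) {
  stopifnot(length(counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (length(total_mapped) != 1L || total_mapped <= 0)
    stop("total_mapped must be a single positive number")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts * 1e9 / total_mapped / gene_lengths
}

#' Transcripts per million
#'
#' Length-normalised counts `R_i = counts_i / length_i` are rescaled so the
#' condition sums to one million: `tpm_i = 1e6 * R_i / sum(R)`.
#'
#' @inheritParams compute_rpkm
#' @return Numeric vector of TPM values (all zero, with a warning, when every
#'   count is zero).
#' @export
compute_tpm <- function(counts, gene_lengths) {
  stopifnot(length(counts) == length(gene_lengths))
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  r <- counts / gene_lengths
  s <- sum(r)
  if (s == 0) {
    warning("all counts zero; TPM undefined, returning zeros")
    return(rep(0, length(counts)))
  }
  1e6 * r / s
}

#' Assign equal-size expression categories
#'
#' Genes are sorted by expression value (ties broken by `gene_id` for
#' determinism) and split into `k` groups whose sizes differ by at most one;
#' when `n %% k != 0` the extra genes go to the lowest categories first.
#' Category 0 is lowest expression, `k - 1` highest.
#'
#' @param values Per-gene expression values.
#' @param k Number of categories (>= 2, <= number of genes).
#' @param gene_ids Optional ids used for deterministic tie-breaking; defaults
#'   to `names(values)` or the index order.
#' @return Integer vector of categories in `0:(k-1)`, in input order.
#' @export
categorize <- function(values, k = 3L, gene_ids = NULL) {
  n <- length(values)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds number of genes (", n, ")")
  if (is.null(gene_ids)) gene_ids <- names(values)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%09d", seq_len(n))
  ord <- order(values, gene_ids)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  cats <- rep.int(seq_len(k) - 1L, sizes)
  out <- integer(n)
  out[ord] <- cats
  out
}

#' Build per-gene expression profiles for one condition
#'
#' @param counts `data.frame` with `gene_id` and `count`.
#' @param genes Gene-model `data.frame` (needs `gene_id`, `length`).
#' @param k Number of expression categories.
#' @param metric Category metric, `"rpkm"` (default) or `"tpm"`.
#' @param total_mapped Optional library-size override; default is the sum of
#'   the per-gene counts.
#' @return `data.frame` with `gene_id`, `count`, `rpkm`, `r_value`, `tpm`,
#'   `category`.
#' @export
expression_profile <- function(counts, genes, k = 3L,
                               metric = c("rpkm", "tpm"),
                               total_mapped = NULL) {
  metric <- match.arg(metric)
  missing <- setdiff(counts$gene_id, genes$gene_id)
  if (length(missing))
    stop("counts reference unknown gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  len <- genes$length[match(counts$gene_id, genes$gene_id)]
  if (is.null(total_mapped)) total_mapped <- sum(counts$count)
  prof <- data.frame(
    gene_id = counts$gene_id,
    count = counts$count,
    rpkm = compute_rpkm(counts$count, len, total_mapped),
    r_value = counts$count / len,
    tpm = compute_tpm(counts$count, len),
    stringsAsFactors = FALSE)
  prof$category <- categorize(prof[[metric]], k, prof$gene_id)
  prof
}

#' Per-gene expression-category shifts between two conditions
#'
#' @param profiles_a,profiles_b Profiles from [expression_profile()] computed
#'   with the same gene set and the same `k`.
#' @return `data.frame` with `gene_id`, `category_a`, `category_b`,
#'   `direction` (`"up"`, `"down"` or `"none"`).
#' @export
category_shifts <- function(profiles_a, profiles_b) {
  only_a <- setdiff(profiles_a$gene_id, profiles_b$gene_id)
  only_b <- setdiff(profiles_b$gene_id, profiles_a$gene_id)
  if (length(only_a) || length(only_b))
    stop("gene sets differ between conditions; offenders: ",
         paste(utils::head(c(only_a, only_b), 10), collapse = ", "))
  idx <- match(profiles_a$gene_id, profiles_b$gene_id)
  ca <- profiles_a$category
  cb <- profiles_b$category[idx]
  data.frame(
    gene_id = profiles_a$gene_id,
    category_a = ca, category_b = cb,
    direction = ifelse(cb > ca, "up", ifelse(cb < ca, "down", "none")),
    stringsAsFactors = FALSE)
}
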