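# Readers and writers for the external formats the pipeline touches.
# All internal coordinates are 1-based inclusive (GFF convention); BED input
# is converted from 0-based half-open on read by rtracklayer.

#' Construct a genome sequence record
#'
#' @param contig_id Contig identifier.
#' @param sequence Nucleotide string; folded to upper case, characters outside
#'   `{A,C,G,T,N}` are replaced by `N`.
#' @param circular Logical; bacterial chromosomes default to circular.
#' @return A list of class `genome_sequence` with fields `contig_id`,
#'   `sequence`, `circular` and `length`.
#' @export
genome_sequence <- function(contig_id, sequence, circular = TRUE) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L, nzchar(contig_id))
  seq <- toupper(as.character(sequence))
  bad <- gsub("[ACGTN]", "", seq)
  if (nzchar(bad)) {
    message(sprintf("contig %s: %d non-ACGTN character(s) mapped to N",
                    contig_id, nchar(bad)))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  structure(
    list(contig_id = contig_id, sequence = seq,
         circular = isTRUE(circular), length = nchar(seq)),
    class = "genome_sequence"
  )
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s: %d bp (%s)\n", x$contig_id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome FASTA file
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param circular Logical flag applied to every record.
#' @return A named list of [genome_sequence()] records.
#' @export
read_genome_fasta <- function(path, circular = TRUE) {
  stopifnot(file.exists(path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate contig id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(seq_along(set), function(i)
    genome_sequence(ids[i], as.character(set[[i]]), circular = circular))
  names(out) <- ids
  out
}

#' Write genome sequences to FASTA
#'
#' @param genomes A [genome_sequence()] or list of them.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_sequence")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(set) <- vapply(genomes, `[[`, "", "contig_id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.mod_types <- c("m6A", "m4C", "modified_base")
.mod_base_for_type <- c(m6A = "A", m4C = "C", modified_base = NA_character_)

.complement <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

.genome_char <- function(genome, pos, strand) {
  ch <- substring(genome$sequence, pos, pos)
  ifelse(strand == "-", .complement(ch), ch)
}

#' Read base-modification calls from an ipdSummary-style GFF3
#'
#' Parses the kinModCall dialect: feature type in column 3 (`m6A`, `m4C` or
#' `modified_base`), PHRED-like score in column 6, and `coverage=` /
#' `IPDRatio=` attribute fields. Unknown attributes are tolerated. Malformed
#' records (non-numeric coordinates or score, unknown feature type) are
#' skipped with a warning; an input where every record is malformed is a hard
#' error. Strand "." is treated as "+" with a warning.
#'
#' Record-level tolerance is the reason this reader parses columns itself
#' rather than delegating to a strict GFF3 importer that aborts on the first
#' malformed row.
#'
#' @param path GFF3 file path.
#' @param min_score Calls with score below this are dropped (default 0, keep
#'   all well-formed calls).
#' @param genome Optional [genome_sequence()] (or named list of them) used to
#'   resolve the base of `modified_base` records and to validate positions.
#' @return A `data.frame` with columns `contig_id`, `position`, `strand`,
#'   `base`, `mod_type`, `nucmod_score`, `coverage`, `ipd_ratio`, `flagged`.
#' @export
read_modifications_gff <- function(path, min_score = 0, genome = NULL) {
  stopifnot(file.exists(path))
  if (inherits(genome, "genome_sequence"))
    genome <- stats::setNames(list(genome), genome$contig_id)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in modification GFF: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_bad <- 0L
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 8L) { n_bad <- n_bad + 1L; next }
    type <- f[3]
    pos <- suppressWarnings(as.integer(f[4]))
    score <- suppressWarnings(as.numeric(f[6]))
    strand <- f[7]
    ok <- type %in% .mod_types && !is.na(pos) && !is.na(score) &&
      strand %in% c("+", "-", ".")
    if (!ok) { n_bad <- n_bad + 1L; next }
    attrs <- if (length(f) >= 9L) f[9] else ""
    cov <- .gff_attr_num(attrs, "coverage")
    ipd <- .gff_attr_num(attrs, "IPDRatio")
    rows[[i]] <- data.frame(
      contig_id = f[1], position = pos, strand = strand,
      mod_type = type, nucmod_score = score,
      coverage = if (is.na(cov)) NA_integer_ else as.integer(round(cov)),
      ipd_ratio = ipd, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (n_bad > 0L)
    warning(sprintf("%s: skipped %d malformed record(s)", path, n_bad))
  if (length(rows) == 0L) stop("all records malformed in ", path)
  mods <- do.call(rbind, rows)
  if (any(mods$strand == ".")) {
    warning(sprintf("%d record(s) with strand '.' treated as '+'",
                    sum(mods$strand == ".")))
    mods$strand[mods$strand == "."] <- "+"
  }
  mods$base <- unname(.mod_base_for_type[mods$mod_type])
  mods$flagged <- FALSE
  if (!is.null(genome)) {
    keep <- rep(TRUE, nrow(mods))
    for (cid in unique(mods$contig_id)) {
      g <- genome[[cid]]
      if (is.null(g)) next
      sel <- mods$contig_id == cid
      off <- sel & (mods$position < 1L | mods$position > g$length)
      if (any(off)) {
        warning(sprintf("%d call(s) outside contig %s dropped", sum(off), cid))
        keep[off] <- FALSE
      }
      sel <- sel & keep
      gchar <- .genome_char(g, mods$position[sel], mods$strand[sel])
      need <- is.na(mods$base[sel])
      base <- mods$base[sel]
      base[need] <- gchar[need]
      # bases other than A/C cannot carry m6A/m4C; keep but flag
      flag <- !(base %in% c("A", "C")) |
        (!need & base != gchar)
      mods$base[sel] <- base
      mods$flagged[sel] <- flag
    }
    mods <- mods[keep, , drop = FALSE]
  }
  n0 <- nrow(mods)
  mods <- mods[mods$nucmod_score >= min_score, , drop = FALSE]
  message(sprintf("%s: kept %d / %d calls at min_score %s",
                  basename(path), nrow(mods), n0, format(min_score)))
  rownames(mods) <- NULL
  mods[c("contig_id", "position", "strand", "base", "mod_type",
         "nucmod_score", "coverage", "ipd_ratio", "flagged")]
}

.gff_attr_num <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), attrs))
  if (length(m) == 0L || !nzchar(m)) return(NA_real_)
  suppressWarnings(as.numeric(sub(paste0(".*", key, "="), "", m)))
}

#' Write base-modification calls as ipdSummary-style GFF3
#'
#' @param mods Modification `data.frame` as returned by
#'   [read_modifications_gff()].
#' @param path Output path.
#' @export
write_modifications_gff <- function(mods, path) {
  attrs <- paste0(
    ifelse(is.na(mods$coverage), "", sprintf("coverage=%d;", mods$coverage)),
    ifelse(is.na(mods$ipd_ratio), "",
           sprintf("IPDRatio=%s;", formatC(mods$ipd_ratio, digits = 6,
                                           format = "g"))))
  attrs[!nzchar(attrs)] <- "."
  lines <- sprintf("%s\tkinModCall\t%s\t%d\t%d\t%s\t%s\t.\t%s",
                   mods$contig_id, mods$mod_type, mods$position,
                   mods$position,
                   formatC(mods$nucmod_score, digits = 6, format = "g"),
                   mods$strand, sub(";$", "", attrs))
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read gene models from an annotation GFF3
#'
#' One gene model per CDS feature (falling back to `gene` features when the
#' file has no CDS). The transcriptional start codon (TSC) position is the
#' feature start on the plus strand and the feature end on the minus strand.
#'
#' @param path GFF3 file path.
#' @return A `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand`, `tsc_position`, `length`.
#' @export
read_annotation_gff <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  sel <- as.character(gr$type) == "CDS"
  if (!any(sel)) sel <- as.character(gr$type) == "gene"
  if (!any(sel)) stop("no CDS or gene features in ", path)
  gr <- gr[sel]
  ids <- as.character(gr$ID)
  if (is.null(gr$ID)) ids <- rep(NA_character_, length(gr))
  miss <- is.na(ids) | !nzchar(ids)
  if (any(miss)) {
    warning(sprintf("%d feature(s) lack an ID; synthetic ids assigned",
                    sum(miss)))
    ids[miss] <- sprintf("feature_%05d", which(miss))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("unstranded gene feature(s) in ", path)
  start <- BiocGenerics::start(gr)
  end <- BiocGenerics::end(gr)
  data.frame(
    gene_id = ids,
    contig_id = as.character(GenomeInfoDb::seqnames(gr)),
    start = start, end = end, strand = strand,
    tsc_position = ifelse(strand == "+", start, end),
    length = end - start + 1L,
    stringsAsFactors = FALSE)
}

#' Write gene models as a GFF3 annotation
#'
#' @param genes Gene-model `data.frame` (see [read_annotation_gff()]).
#' @param path Output path.
#' @export
write_annotation_gff <- function(genes, path) {
  lines <- sprintf("%s\tmethylink\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                   genes$contig_id, genes$start, genes$end, genes$strand,
                   genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read mobile-genetic-element / genomic-island intervals from BED
#'
#' BED's 0-based half-open coordinates are converted to 1-based inclusive.
#'
#' @param path BED file path.
#' @return A `data.frame` with columns `contig_id`, `start`, `end`.
#' @export
read_islands_bed <- function(path) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(contig_id = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

#' Read a per-condition gene count table
#'
#' @param path TSV with header columns `gene_id` and `count`.
#' @return A `data.frame` with those two columns.
#' @export
read_counts_tsv <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_id", "count") %in% names(tab)))
    stop("count table must have columns gene_id and count: ", path)
  tab$count <- as.numeric(tab$count)
  if (any(is.na(tab$count) | tab$count < 0))
    stop("negative or non-numeric counts in ", path)
  tab[c("gene_id", "count")]
}

#' Write a per-condition gene count table
#' @param counts `data.frame` with `gene_id` and `count`.
#' @param path Output path.
#' @export
write_counts_tsv <- function(counts, path) {
  write_table(counts[c("gene_id", "count")], path)
}

#' Write a homogeneous result table as TSV
#'
#' Tab-separated with a header row; numeric columns rendered with 6
#' significant digits so that files round-trip through [read_table()].
#'
#' @param records A `data.frame` of one result type (may have zero rows).
#' @param path Output path.
#' @export
write_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- ifelse(is.na(out[[j]]), NA,
                         formatC(out[[j]], digits = 6, format = "g"))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_table <- function(path) {
  stopifnot(file.exists(path))
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
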