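# Shared in-code fixtures and independent oracles.

make_mods <- function(position, strand, base = "A", score = 100,
                      contig = "c1") {
  n <- length(position)
  data.frame(contig_id = rep_len(contig, n), position = as.integer(position),
             strand = rep_len(strand, n), base = rep_len(base, n),
             mod_type = ifelse(rep_len(base, n) == "A", "m6A", "m4C"),
             nucmod_score = rep_len(score, n),
             coverage = rep_len(40L, n), ipd_ratio = NA_real_,
             flagged = FALSE, stringsAsFactors = FALSE)
}

make_genes <- function(start, end, strand, contig = "c1") {
  n <- length(start)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)),
             contig_id = rep_len(contig, n),
             start = as.integer(start), end = as.integer(end),
             strand = strand,
             tsc_position = ifelse(strand == "+", as.integer(start),
                                   as.integer(end)),
             length = as.integer(end - start + 1L),
             stringsAsFactors = FALSE)
}

make_shifts <- function(gene_id, direction) {
  data.frame(gene_id = gene_id,
             category_a = 0L, category_b = 0L,
             direction = direction, stringsAsFactors = FALSE)
}

write_gff_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}

# Independent per-gene tally oracle for window_contingency: explicit genomic
# interval arithmetic, no relative-coordinate machinery. Linear genomes only.
oracle_window_tally <- function(genes, mods_a, mods_b, shifts, offset,
                                window, cutoff = 0) {
  cells <- c(a = 0L, b = 0L, c = 0L, d = 0L)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    dir <- shifts$direction[shifts$gene_id == g$gene_id]
    if (length(dir) != 1L || dir == "none") next
    if (g$strand == "+") {
      lo <- g$tsc_position + offset
      hi <- g$tsc_position + offset + window - 1L
    } else {
      lo <- g$tsc_position - offset - window + 1L
      hi <- g$tsc_position - offset
    }
    count <- function(m) sum(m$contig_id == g$contig_id &
                               m$strand == g$strand &
                               m$nucmod_score >= cutoff &
                               m$position >= lo & m$position <= hi)
    delta <- count(mods_b) - count(mods_a)
    if (delta == 0L) next
    cell <- if (dir == "up" && delta > 0) "a" else if (dir == "up") "b"
    else if (delta > 0) "c" else "d"
    cells[cell] <- cells[cell] + 1L
  }
  cells
}
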