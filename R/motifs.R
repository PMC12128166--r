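# IUPAC motif scanning and canonical / non-canonical classification of
# base-modification calls.

.iupac_ok <- function(chars) chars %in% names(Biostrings::IUPAC_CODE_MAP)

.iupac_admits <- function(letter, base) {
  grepl(base, Biostrings::IUPAC_CODE_MAP[[letter]], fixed = TRUE)
}

#' Define a recognition motif with methylatable offsets
#'
#' Motifs are written with lowercase letters marking methylated positions,
#' e.g. `"AgGCcT"` (cytosine methylated at offset 4 on the motif strand, the
#' guanine at offset 1 marking the methylated cytosine of the complement
#' strand) and `"GaTNNNNNGtGG"` (adenine at offset 1 forward, offset 9 on the
#' complement). A lowercase `A`/`C` is a forward methylatable offset; a
#' lowercase `G`/`T` marks methylation of its complement base on the reverse
#' strand.
#'
#' @param iupac Motif string over IUPAC codes with lowercase methylation
#'   marks.
#' @param name Optional motif name; defaults to the motif string.
#' @return A list of class `motif_spec` with fields `name`, `iupac`
#'   (uppercase), `length`, `fwd_methyl_offsets`, `rev_methyl_offsets`
#'   (0-based).
#' @export
motif_spec <- function(iupac, name = iupac) {
  chars <- strsplit(iupac, "")[[1]]
  up <- toupper(chars)
  if (!all(.iupac_ok(up)))
    stop("invalid IUPAC letter(s) in motif: ",
         paste(unique(up[!.iupac_ok(up)]), collapse = ", "))
  lower <- which(chars != up) - 1L  # 0-based marked offsets
  fwd <- integer(0); rev <- integer(0)
  for (o in lower) {
    l <- up[o + 1L]
    if (l %in% c("A", "C")) fwd <- c(fwd, o)
    else if (l %in% c("G", "T")) rev <- c(rev, o)
    else stop("methylation mark at offset ", o,
              " is neither A/C nor G/T: ", l)
  }
  structure(list(name = name, iupac = paste(up, collapse = ""),
                 length = length(up),
                 fwd_methyl_offsets = fwd, rev_methyl_offsets = rev),
            class = "motif_spec")
}

#' The two canonical recognition motifs
#'
#' `AgGCcT` (m4C, both strands; a palindrome) and `GaTNNNNNGtGG` (m6A on both
#' strands although the motif is not palindromic).
#'
#' @return Named list of two [motif_spec()] objects.
#' @export
canonical_motifs <- function() {
  list(AGGCCT = motif_spec("AgGCcT", "AGGCCT"),
       GATNNNNNGTGG = motif_spec("GaTNNNNNGtGG", "GATNNNNNGTGG"))
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.is_palindrome <- function(iupac) identical(iupac, .revcomp(iupac))

.wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

#' Scan a genome for motif occurrences on both strands
#'
#' Forward-strand matches are reported with orientation `+`; matches of the
#' reverse complement with orientation `-`. Palindromic motifs are reported
#' once (orientation `+`). Circular genomes are scanned across the origin by
#' appending the first `length(motif) - 1` bases and de-duplicating by
#' modulo position. Overlapping occurrences are all reported.
#'
#' @param genome A [genome_sequence()].
#' @param motif A [motif_spec()].
#' @return A list of class `motif_sites`: `sites` (`data.frame` with
#'   `site_id`, `contig_id`, `start`, `end`, `orientation`, `motif`; `end`
#'   may exceed the contig length for origin-spanning sites) and `positions`
#'   (`data.frame` with `site_id`, `position`, `strand`, `base` — one row
#'   per methylatable position, positions normalised into the contig).
#' @export
scan_motif <- function(genome, motif) {
  stopifnot(inherits(genome, "genome_sequence"), inherits(motif, "motif_spec"))
  L <- genome$length
  if (motif$length > L) stop("motif longer than genome")
  seq <- genome$sequence
  ext <- if (genome$circular && L > motif$length)
    paste0(seq, substr(seq, 1L, motif$length - 1L)) else seq
  subject <- Biostrings::DNAString(ext)
  find <- function(pattern) {
    m <- Biostrings::matchPattern(pattern, subject, fixed = "subject")
    starts <- BiocGenerics::start(m)
    sort(unique(.wrap_pos(starts, L)))
  }
  fwd_starts <- find(motif$iupac)
  if (.is_palindrome(motif$iupac)) {
    starts <- fwd_starts
    orient <- rep("+", length(starts))
  } else {
    rev_starts <- find(.revcomp(motif$iupac))
    starts <- c(fwd_starts, rev_starts)
    orient <- c(rep("+", length(fwd_starts)), rep("-", length(rev_starts)))
  }
  if (length(starts) == 0L) {
    sites <- data.frame(site_id = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        orientation = character(), motif = character(),
                        stringsAsFactors = FALSE)
    pos <- data.frame(site_id = character(), position = integer(),
                      strand = character(), base = character(),
                      stringsAsFactors = FALSE)
    return(structure(list(sites = sites, positions = pos),
                     class = "motif_sites"))
  }
  ord <- order(starts, orient)
  starts <- starts[ord]; orient <- orient[ord]
  ids <- sprintf("%s_%s_%d%s", motif$name, genome$contig_id, starts,
                 ifelse(orient == "+", "F", "R"))
  sites <- data.frame(site_id = ids, contig_id = genome$contig_id,
                      start = starts, end = starts + motif$length - 1L,
                      orientation = orient, motif = motif$name,
                      stringsAsFactors = FALSE)
  pos <- .methylatable_positions(sites, motif, L)
  structure(list(sites = sites, positions = pos), class = "motif_sites")
}

#' @export
print.motif_sites <- function(x, ...) {
  cat(sprintf("<motif_sites> %s: %d site(s), %d methylatable position(s)\n",
              if (nrow(x$sites)) x$sites$motif[1] else "?",
              nrow(x$sites), nrow(x$positions)))
  invisible(x)
}

# Map motif offsets to genomic (position, strand, expected base), wrapping
# origin-spanning sites back into 1..L.
.methylatable_positions <- function(sites, motif, contig_len) {
  letters <- strsplit(motif$iupac, "")[[1]]
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    rows <- list()
    for (o in motif$fwd_methyl_offsets) {
      p <- if (s$orientation == "+") s$start + o else s$end - o
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = s$site_id, position = .wrap_pos(p, contig_len),
        strand = s$orientation, base = letters[o + 1L],
        stringsAsFactors = FALSE)
    }
    for (o in motif$rev_methyl_offsets) {
      p <- if (s$orientation == "+") s$start + o else s$end - o
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = s$site_id, position = .wrap_pos(p, contig_len),
        strand = if (s$orientation == "+") "-" else "+",
        base = .complement(letters[o + 1L]),
        stringsAsFactors = FALSE)
    }
    out[[i]] <- do.call(rbind, rows)
  }
  do.call(rbind, out)
}

.all_positions <- function(sites) {
  if (inherits(sites, "motif_sites")) return(sites$positions)
  do.call(rbind, lapply(sites, function(s) s$positions))
}

#' Split modification calls into canonical and non-canonical sets
#'
#' A call is canonical iff its `(contig, position, strand)` coincides with a
#' methylatable position of some motif site and its base matches the motif's
#' methylatable base; base mismatches at a matching position are demoted to
#' non-canonical with a warning.
#'
#' @param mods Modification calls (see [read_modifications_gff()]).
#' @param sites A `motif_sites` object or a list of them (all motifs).
#' @return List with elements `canonical` and `noncanonical`, partitioning
#'   `mods`.
#' @export
classify_modifications <- function(mods, sites) {
  pos <- .all_positions(sites)
  mkey <- paste(mods$contig_id, mods$position, mods$strand)
  pkey <- paste(.position_contigs(sites), pos$position, pos$strand)
  hit <- match(mkey, pkey)
  canonical <- !is.na(hit)
  if (any(canonical)) {
    base_ok <- mods$base[canonical] == pos$base[hit[canonical]]
    if (any(!base_ok)) {
      warning(sprintf(
        "%d call(s) at motif positions with mismatching base demoted to non-canonical",
        sum(!base_ok)))
      canonical[canonical][!base_ok] <- FALSE
    }
  }
  list(canonical = mods[canonical, , drop = FALSE],
       noncanonical = mods[!canonical, , drop = FALSE])
}

# contig of each methylatable position, recovered from the sites table
.position_contigs <- function(sites) {
  if (inherits(sites, "motif_sites")) sites <- list(sites)
  unlist(lapply(sites, function(s) {
    s$sites$contig_id[match(s$positions$site_id, s$sites$site_id)]
  }), use.names = FALSE)
}

#' Methylation status of motif sites
#'
#' A site is `fully_methylated` when every methylatable position carries a
#' call with score at or above the cutoff, `unmethylated` when none does,
#' and `partially_methylated` otherwise. The default cutoff 21 encodes the
#' convention that calls scoring 21 and above count as methylated.
#'
#' @param sites A `motif_sites` object.
#' @param mods Modification calls (unfiltered; the cutoff is applied here).
#' @param score_cutoff Methylation score threshold (default 21).
#' @return List with `status` (`data.frame`: `site_id`, `status`,
#'   `n_positions`, `n_methylated`, `max_score`) and `summary` (named counts
#'   `n_fully`, `n_partially`, `n_unmethylated`).
#' @export
motif_status <- function(sites, mods, score_cutoff = 21) {
  stopifnot(inherits(sites, "motif_sites"))
  pos <- sites$positions
  pkey <- paste(.position_contigs(sites), pos$position, pos$strand)
  mkey <- paste(mods$contig_id, mods$position, mods$strand)
  score <- vapply(pkey, function(k) {
    s <- mods$nucmod_score[mkey == k]
    if (length(s)) max(s) else NA_real_
  }, numeric(1))
  meth <- !is.na(score) & score >= score_cutoff
  by_site <- split(meth, pos$site_id)
  site_ids <- sites$sites$site_id
  by_site <- by_site[site_ids]
  n_pos <- vapply(by_site, length, 0L)
  n_meth <- vapply(by_site, sum, 0L)
  status <- ifelse(n_meth == n_pos, "fully_methylated",
                   ifelse(n_meth == 0L, "unmethylated",
                          "partially_methylated"))
  max_score <- vapply(split(score, pos$site_id)[site_ids], function(s)
    if (all(is.na(s))) NA_real_ else max(s, na.rm = TRUE), numeric(1))
  st <- data.frame(site_id = site_ids, status = status,
                   n_positions = n_pos, n_methylated = n_meth,
                   max_score = max_score,
                   stringsAsFactors = FALSE, row.names = NULL)
  summary <- c(n_fully = sum(status == "fully_methylated"),
               n_partially = sum(status == "partially_methylated"),
               n_unmethylated = sum(status == "unmethylated"))
  list(status = st, summary = summary)
}
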