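# Indel extraction from spliced read alignments.
#
# Events come straight from the CIGAR: one event per I/D operator. An
# insertion is anchored at the reference base immediately left of the
# inserted bases; a deletion at the first deleted reference base. Events
# are left-aligned against the reference before merging so that
# repeat-context indels collapse to a single key per locus.
#
# Depth at a site counts reads whose alignment spans it: for an insertion,
# reads with aligned (M/=/X) bases at both flanking reference positions
# (within one gap-free aligned block, which includes carriers of any
# insertion allele there); for a deletion, reads carrying the D operator
# plus reference-supporting reads whose gap-free block crosses either
# breakpoint of the deleted interval.

CIGAR_REF_OPS <- c("M", "=", "X", "D", "N")
CIGAR_QUERY_OPS <- c("M", "=", "X", "I", "S")

#' Read alignment records from a SAM or BAM file
#'
#' Only the fields the caller uses are loaded: QNAME, FLAG, RNAME, POS,
#' CIGAR, SEQ. Unmapped, secondary and supplementary records are dropped,
#' so multi-mapped reads are counted once via their primary alignment.
#'
#' @param path Path to a `.sam` (plain text) or `.bam` file.
#' @return data.frame with columns qname, flag, rname, pos, cigar, seq.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  df <- data.frame(qname = b$qname, flag = b$flag,
                   rname = as.character(b$rname), pos = b$pos,
                   cigar = b$cigar, seq = as.character(b$seq),
                   stringsAsFactors = FALSE)
  keep <- !is.na(df$pos) &
    bitwAnd(df$flag, 4L) == 0L &      # mapped
    bitwAnd(df$flag, 256L) == 0L &    # primary
    bitwAnd(df$flag, 2048L) == 0L     # non-supplementary
  df[keep, , drop = FALSE]
}

# parse CIGAR strings into a long table: read_i, op, len, plus the 1-based
# reference start and query start of each operator
parse_cigar_ops <- function(cigars, pos) {
  if (any(is.na(cigars) | cigars == "*")) stop("invalid CIGAR in alignment input")
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigars)
  toks <- regmatches(cigars, m)
  if (any(vapply(toks, function(t) sum(nchar(t)), 0L) != nchar(cigars))) {
    stop("unparseable CIGAR string")
  }
  nops <- lengths(toks)
  flat <- unlist(toks, use.names = FALSE)
  len <- as.integer(sub("[A-Z=]$", "", flat))
  op <- sub("^\\d+", "", flat)
  read_i <- rep(seq_along(cigars), nops)
  ref_adv <- ifelse(op %in% CIGAR_REF_OPS, len, 0L)
  query_adv <- ifelse(op %in% CIGAR_QUERY_OPS, len, 0L)
  # per-read cumulative offsets (exclusive) via group-wise cumsum
  cum_ref <- stats::ave(ref_adv, read_i, FUN = function(x) cumsum(x) - x)
  cum_query <- stats::ave(query_adv, read_i, FUN = function(x) cumsum(x) - x)
  data.frame(read_i = read_i, op = op, len = len,
             ref_start = rep(pos, nops) + as.integer(cum_ref),
             query_start = as.integer(cum_query) + 1L,
             stringsAsFactors = FALSE)
}

# left-align one event against the reference scaffold string
left_align_event <- function(kind, pos, seq, refseq) {
  L <- nchar(seq)
  if (kind == "insertion") {
    # anchored at pos; shifts while the last inserted base equals ref[pos]
    while (pos >= 1L) {
      rb <- genome_slice_chr(refseq, pos, pos)
      if (rb != substr(seq, L, L)) break
      seq <- paste0(rb, substr(seq, 1L, L - 1L))
      pos <- pos - 1L
    }
  } else {
    # first deleted base at pos; shifts while ref[pos-1] == ref[pos+L-1]
    while (pos > 1L) {
      if (genome_slice_chr(refseq, pos - 1L, pos - 1L) !=
          genome_slice_chr(refseq, pos + L - 1L, pos + L - 1L)) break
      pos <- pos - 1L
      seq <- genome_slice_chr(refseq, pos, pos + L - 1L)
    }
  }
  list(pos = pos, seq = seq)
}

genome_slice_chr <- function(x, s, e) {
  if (is.character(x)) substr(x, s, e) else as.character(Biostrings::subseq(x, s, e))
}

#' Extract raw indel events from one aligned read
#'
#' One event per I/D CIGAR operator. Insertions are anchored at the
#' reference base immediately left of the insertion point; deletions at the
#' first deleted reference base. Soft clips, matches and splice gaps (N)
#' produce nothing. Events are left-aligned when the genome is supplied.
#'
#' @param read One-row data.frame (or list) with fields rname, pos, cigar,
#'   seq, flag, qname.
#' @param genome Optional [load_genome()] result; required to fill in
#'   deleted-base sequences and to left-align.
#' @return data.frame with columns scaffold, genomic_pos, kind, sequence,
#'   read_id (possibly zero rows).
#' @export
extract_events <- function(read, genome = NULL) {
  read <- as.data.frame(read, stringsAsFactors = FALSE)
  if (bitwAnd(read$flag, 4L) != 0L) {
    return(data.frame(scaffold = character(0), genomic_pos = integer(0),
                      kind = character(0), sequence = character(0),
                      read_id = character(0)))
  }
  extract_events_batch(read, genome)
}

# vectorized event extraction over a reads data.frame
extract_events_batch <- function(reads, genome = NULL) {
  empty <- data.frame(scaffold = character(0), genomic_pos = integer(0),
                      kind = character(0), sequence = character(0),
                      read_id = character(0), stringsAsFactors = FALSE)
  if (nrow(reads) == 0L) return(empty)
  ops <- parse_cigar_ops(reads$cigar, reads$pos)
  ev <- ops[ops$op %in% c("I", "D"), , drop = FALSE]
  if (nrow(ev) == 0L) return(empty)
  kind <- ifelse(ev$op == "I", "insertion", "deletion")
  gpos <- ifelse(ev$op == "I", ev$ref_start - 1L, ev$ref_start)
  scaf <- reads$rname[ev$read_i]
  seqs <- character(nrow(ev))
  ins <- which(ev$op == "I")
  seqs[ins] <- substr(reads$seq[ev$read_i[ins]], ev$query_start[ins],
                      ev$query_start[ins] + ev$len[ins] - 1L)
  del <- which(ev$op == "D")
  if (length(del)) {
    if (is.null(genome)) {
      seqs[del] <- strrep("N", ev$len[del])
    } else {
      seqs[del] <- vapply(del, function(i) {
        genome_slice(genome, scaf[i], ev$ref_start[i],
                     ev$ref_start[i] + ev$len[i] - 1L)
      }, character(1))
    }
  }
  out <- data.frame(scaffold = scaf, genomic_pos = as.integer(gpos),
                    kind = kind, sequence = toupper(seqs),
                    read_id = reads$qname[ev$read_i],
                    stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    for (i in seq_len(nrow(out))) {
      la <- left_align_event(out$kind[i], out$genomic_pos[i], out$sequence[i],
                             genome[[out$scaffold[i]]])
      out$genomic_pos[i] <- la$pos
      out$sequence[i] <- la$seq
    }
  }
  out
}

# gap-free aligned blocks (merged across I operators, which do not advance
# the reference) per read: read_i, rname, start, end
aligned_blocks <- function(reads) {
  if (nrow(reads) == 0L) {
    return(data.frame(read_i = integer(0), rname = character(0),
                      start = integer(0), end = integer(0)))
  }
  ops <- parse_cigar_ops(reads$cigar, reads$pos)
  mm <- ops[ops$op %in% c("M", "=", "X"), , drop = FALSE]
  mm$end <- mm$ref_start + mm$len - 1L
  # merge blocks adjacent in reference space (separated only by I)
  o <- order(mm$read_i, mm$ref_start)
  mm <- mm[o, , drop = FALSE]
  new_grp <- c(TRUE, mm$read_i[-1L] != mm$read_i[-nrow(mm)] |
                 mm$ref_start[-1L] != mm$end[-nrow(mm)] + 1L)
  first <- which(new_grp)
  last <- c(first[-1L] - 1L, nrow(mm))
  data.frame(read_i = mm$read_i[first],
             rname = reads$rname[mm$read_i[first]],
             start = mm$ref_start[first],
             end = mm$end[last],
             stringsAsFactors = FALSE)
}

#' Precompute per-population alignment indexes
#'
#' Parses CIGARs once, extracting normalized indel events and gap-free
#' aligned blocks for depth computation. Used by [pileup_sites()] and
#' [compare_all()].
#'
#' @param reads data.frame from [read_alignments()].
#' @param genome [load_genome()] result.
#' @return List with `events`, `blocks`, `n_reads`.
#' @export
index_alignments <- function(reads, genome) {
  list(events = extract_events_batch(reads, genome),
       blocks = aligned_blocks(reads),
       n_reads = nrow(reads))
}

# spanning-read depth at given loci. loci: data.frame(scaffold, genomic_pos,
# kind, len). Returns integer vector.
depth_at <- function(idx, loci) {
  ev <- idx$events
  bl <- idx$blocks
  vapply(seq_len(nrow(loci)), function(i) {
    scaf <- loci$scaffold[i]; p <- loci$genomic_pos[i]
    if (loci$kind[i] == "insertion") {
      # blocks are merged across I operators, so carriers of any insertion
      # allele at p are covered by this rule along with plain spanning reads
      cover <- bl$read_i[bl$rname == scaf & bl$start <= p & bl$end >= p + 1L]
      length(unique(cover))
    } else {
      # a read is informative for a deletion if it carries the D operator,
      # or its gap-free block crosses a breakpoint of the deleted interval
      # (reference-supporting); partial overlap without a breakpoint is
      # ambiguous and not counted
      e <- p + loci$len[i] - 1L
      lb <- max(p - 1L, 1L)
      cover <- bl$read_i[bl$rname == scaf &
                           ((bl$start <= lb & bl$end >= p) |
                              (bl$start <= e & bl$end >= e + 1L))]
      carry <- ev$read_id[ev$scaffold == scaf & ev$kind == "deletion" &
                            ev$genomic_pos == p]
      length(unique(cover)) + length(unique(carry))
    }
  }, integer(1))
}

#' Aggregate indel events into per-site pileup records
#'
#' Events sharing (scaffold, position, kind, sequence) merge into one site;
#' distinct indel alleles at one position stay distinct. Depth counts every
#' read whose alignment spans the site (see module notes), so
#' `allele_fraction = alt_count / depth` is the "percent genotype" of the
#' screen.
#'
#' @param reads data.frame from [read_alignments()] (or an
#'   [index_alignments()] result).
#' @param genome [load_genome()] result.
#' @param population Population label attached to every site.
#' @return data.frame of sites sorted by scaffold, position, kind,
#'   sequence: scaffold, genomic_pos, kind, sequence, population, depth,
#'   alt_count, allele_fraction.
#' @export
pileup_sites <- function(reads, genome, population) {
  idx <- if (is.data.frame(reads)) index_alignments(reads, genome) else reads
  ev <- idx$events
  empty <- data.frame(scaffold = character(0), genomic_pos = integer(0),
                      kind = character(0), sequence = character(0),
                      population = character(0), depth = integer(0),
                      alt_count = integer(0), allele_fraction = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) return(empty)
  key <- paste(ev$scaffold, ev$genomic_pos, ev$kind, ev$sequence, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  sites <- data.frame(
    scaffold = vapply(parts, `[[`, "", 1L),
    genomic_pos = as.integer(vapply(parts, `[[`, "", 2L)),
    kind = vapply(parts, `[[`, "", 3L),
    sequence = vapply(parts, `[[`, "", 4L),
    population = population,
    alt_count = as.integer(agg$Freq),
    stringsAsFactors = FALSE)
  sites$len <- nchar(sites$sequence)
  sites$depth <- depth_at(idx, sites)
  sites$allele_fraction <- sites$alt_count / sites$depth
  sites$len <- NULL
  sites <- sites[order(sites$scaffold, sites$genomic_pos, sites$kind,
                       sites$sequence), , drop = FALSE]
  rownames(sites) <- NULL
  sites[, c("scaffold", "genomic_pos", "kind", "sequence", "population",
            "depth", "alt_count", "allele_fraction")]
}
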