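# Gene models: reference genome container and exact genomic <-> cDNA <-> exon
# coordinate arithmetic. Coordinates are 1-based, fully closed, everywhere.
# cDNA positions run in transcript orientation: for a "-" strand gene, exon
# ordinal 1 is the exon with the highest genomic coordinates.

#' Load a reference genome from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by scaffold id (first
#'   whitespace-delimited token of each header). Scaffold lengths are
#'   `BiocGenerics::width()` of the result.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in FASTA: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate scaffold ids in ", path, ": ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs
}

scaffold_length <- function(genome, scaffold) {
  i <- match(scaffold, names(genome))
  if (anyNA(i)) stop("unknown scaffold: ", paste(scaffold[is.na(i)], collapse = ", "))
  BiocGenerics::width(genome)[i]
}

genome_slice <- function(genome, scaffold, start, end) {
  as.character(Biostrings::subseq(genome[[scaffold]], start, end))
}

#' Construct a single-transcript gene model
#'
#' Exons are supplied in transcript order (ordinal 1 first). For a minus
#' strand gene ordinal 1 must carry the highest genomic coordinates.
#'
#' @param gene_id Stable gene identifier.
#' @param gene_name Display name used in mutation names.
#' @param scaffold Scaffold id.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends Integer vectors of 1-based inclusive genomic
#'   coordinates, one entry per exon, in transcript order.
#' @param cds_offset 0-based offset of the first CDS base on the cDNA
#'   (default 0: CDS starts at cDNA base 1).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_name, scaffold, strand,
                       exon_starts, exon_ends, cds_offset = 0L) {
  stopifnot(length(exon_starts) == length(exon_ends), length(exon_starts) >= 1L)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exon_starts <- as.integer(exon_starts)
  exon_ends <- as.integer(exon_ends)
  if (any(exon_starts > exon_ends)) stop("exon start > end in gene ", gene_id)
  if (any(exon_starts < 1L)) stop("exon coordinates must be >= 1")
  if (cds_offset < 0L) stop("cds_offset must be >= 0")
  n <- length(exon_starts)
  # transcript order sanity + non-overlap
  g_sorted <- if (strand == "+") exon_starts else rev(exon_starts)
  if (n > 1L && any(diff(g_sorted) <= 0L)) {
    stop("exons of gene ", gene_id, " are not in transcript order for strand ", strand)
  }
  e_sorted <- if (strand == "+") exon_ends else rev(exon_ends)
  if (n > 1L && any(g_sorted[-1L] <= e_sorted[-n])) {
    stop("overlapping exons in gene ", gene_id)
  }
  widths <- exon_ends - exon_starts + 1L
  structure(list(
    gene_id = gene_id, gene_name = gene_name, scaffold = scaffold,
    strand = strand,
    exons = data.frame(genomic_start = exon_starts, genomic_end = exon_ends,
                       ordinal = seq_len(n)),
    cdna_length = sum(widths),
    cds_offset = as.integer(cds_offset),
    cum_end = cumsum(widths)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d strand %s, %d exon(s), cDNA %d bp, cds_offset %d\n",
              x$gene_name, x$gene_id, x$scaffold,
              min(x$exons$genomic_start), max(x$exons$genomic_end),
              x$strand, nrow(x$exons), x$cdna_length, x$cds_offset))
  invisible(x)
}

gene_span <- function(model) {
  c(min(model$exons$genomic_start), max(model$exons$genomic_end))
}

# cDNA interval [cs, ce] of exon i
exon_cdna_span <- function(model, i) {
  cs <- if (i > 1L) model$cum_end[i - 1L] + 1L else 1L
  c(cs, model$cum_end[i])
}

#' Map genomic positions to cDNA coordinates
#'
#' @param model A [gene_model()].
#' @param gpos Integer vector of 1-based genomic positions on the model's
#'   scaffold.
#' @return Integer vector of 1-based cDNA positions; `NA` for intronic (or
#'   otherwise non-exonic) positions.
#' @export
genomic_to_cdna <- function(model, gpos) {
  gpos <- as.integer(gpos)
  if (any(gpos < 1L, na.rm = TRUE)) stop("genomic position must be >= 1")
  ex <- model$exons
  vapply(gpos, function(g) {
    i <- which(g >= ex$genomic_start & g <= ex$genomic_end)
    if (length(i) == 0L) return(NA_integer_)
    i <- i[1L]
    before <- if (i > 1L) model$cum_end[i - 1L] else 0L
    off <- if (model$strand == "+") g - ex$genomic_start[i] else ex$genomic_end[i] - g
    before + off + 1L
  }, integer(1))
}

#' Map cDNA positions to genomic coordinates
#'
#' Inverse of [genomic_to_cdna()] over exonic bases.
#'
#' @inheritParams genomic_to_cdna
#' @param cpos Integer vector of 1-based cDNA positions in
#'   `[1, cdna_length]`.
#' @return Integer vector of genomic positions.
#' @export
cdna_to_genomic <- function(model, cpos) {
  cpos <- as.integer(cpos)
  if (any(cpos < 1L | cpos > model$cdna_length)) {
    stop("cDNA position out of range [1, ", model$cdna_length, "] for gene ",
         model$gene_name)
  }
  ex <- model$exons
  vapply(cpos, function(cp) {
    i <- findInterval(cp - 1L, c(0L, model$cum_end), rightmost.closed = FALSE)
    before <- if (i > 1L) model$cum_end[i - 1L] else 0L
    off <- cp - before - 1L
    if (model$strand == "+") ex$genomic_start[i] + off else ex$genomic_end[i] - off
  }, integer(1))
}

#' Exon ordinal containing a cDNA position
#'
#' @inheritParams cdna_to_genomic
#' @return For scalar `cpos`, an integer vector `c(ordinal, n_exons)`,
#'   mirroring the "exon (total exons)" presentation of screened lesions.
#' @export
exon_of <- function(model, cpos) {
  cpos <- as.integer(cpos)
  if (length(cpos) != 1L) stop("exon_of expects a single cDNA position")
  if (cpos < 1L || cpos > model$cdna_length) {
    stop("cDNA position out of range for gene ", model$gene_name)
  }
  i <- findInterval(cpos - 1L, c(0L, model$cum_end))
  c(ordinal = i, n_exons = nrow(model$exons))
}

#' Distance from a cDNA position to the nearest splice boundary
#'
#' Distance is measured in cDNA bp within the containing exon; 0 means the
#' position is the first or last base of an internal exon. Transcript
#' termini (the outer edges of the first and last exon) are not splice
#' boundaries unless `include_termini = TRUE`: a lesion in a terminal exon
#' can sit arbitrarily close to the transcript end without being a splice
#' artifact.
#'
#' @inheritParams cdna_to_genomic
#' @param include_termini Treat transcript ends as boundaries too.
#' @return Numeric distance in bp (`Inf` for a single-exon gene with
#'   `include_termini = FALSE`).
#' @export
exon_boundary_distance <- function(model, cpos, include_termini = FALSE) {
  cpos <- as.integer(cpos)
  vapply(cpos, function(cp) {
    if (cp < 1L || cp > model$cdna_length) {
      stop("cDNA position out of range for gene ", model$gene_name)
    }
    i <- findInterval(cp - 1L, c(0L, model$cum_end))
    sp <- exon_cdna_span(model, i)
    dl <- cp - sp[1L]
    dr <- sp[2L] - cp
    n <- nrow(model$exons)
    if (!include_termini) {
      if (i == 1L) dl <- Inf
      if (i == n) dr <- Inf
    }
    min(dl, dr)
  }, numeric(1))
}

#' Load gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon features linked by `ID`/`Parent` attributes. One
#' transcript per gene is modeled; when a gene has several mRNAs the longest
#' (summed exon length) is kept with a warning. Exon ordinals are assigned
#' in transcript orientation.
#'
#' @param path GFF3 file path.
#' @param genome Optional [load_genome()] result used to validate that
#'   every exon lies inside its scaffold.
#' @param cds_offsets Optional named integer vector of per-gene CDS offsets
#'   (names are gene names).
#' @return Named list of [gene_model()] objects keyed by gene name.
#' @export
load_gene_models <- function(path, genome = NULL, cds_offsets = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  seqn <- as.character(GenomeInfoDb::seqnames(gr))
  starts <- BiocGenerics::start(gr)
  ends <- BiocGenerics::end(gr)
  strands <- as.character(BiocGenerics::strand(gr))
  ids <- as.character(md$ID)
  parents <- vapply(as.list(md$Parent), function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1))
  names_attr <- if ("Name" %in% colnames(md)) as.character(md$Name) else rep(NA_character_, length(gr))

  gene_idx <- which(types == "gene")
  mrna_idx <- which(types %in% c("mRNA", "transcript"))
  exon_idx <- which(types == "exon")
  if (length(gene_idx) == 0L) stop("no gene features in ", path)

  models <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    gname <- if (!is.na(names_attr[gi])) names_attr[gi] else gid
    tr <- mrna_idx[parents[mrna_idx] %in% gid]
    if (length(tr) == 0L) {
      warning("gene ", gid, " has no mRNA feature; skipped")
      next
    }
    if (length(tr) > 1L) {
      lens <- vapply(tr, function(ti) {
        exs <- exon_idx[parents[exon_idx] %in% ids[ti]]
        sum(ends[exs] - starts[exs] + 1L)
      }, numeric(1))
      warning("gene ", gid, " has ", length(tr),
              " transcripts; keeping the longest")
      tr <- tr[which.max(lens)]
    }
    exs <- exon_idx[parents[exon_idx] %in% ids[tr]]
    if (length(exs) == 0L) stop("transcript ", ids[tr], " has no exons")
    strand <- strands[tr]
    if (!strand %in% c("+", "-")) stop("transcript ", ids[tr], " lacks a strand")
    ord <- order(starts[exs], decreasing = (strand == "-"))
    exs <- exs[ord]
    scaf <- seqn[tr]
    if (!is.null(genome)) {
      if (!scaf %in% names(genome)) stop("unknown scaffold in GFF3: ", scaf)
      slen <- scaffold_length(genome, scaf)
      if (any(ends[exs] > slen) || any(starts[exs] < 1L)) {
        stop("exon outside scaffold bounds for gene ", gid, " on ", scaf)
      }
    }
    off <- 0L
    if (!is.null(cds_offsets) && gname %in% names(cds_offsets)) {
      off <- as.integer(cds_offsets[[gname]])
    }
    models[[gname]] <- gene_model(gid, gname, scaf, strand,
                                  starts[exs], ends[exs], cds_offset = off)
  }
  models
}

# index models by scaffold for the screen
models_by_scaffold <- function(models) {
  split(models, vapply(models, `[[`, "", "scaffold"))
}
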