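# Synthetic fixture generator: a toy multi-scaffold genome whose gene models
# carry the seven validated lesions, per-population allele sequences,
# spliced read alignments written as SAM, an outgroup FASTA, and truth
# tables. Everything is a deterministic function of (spec, seed).
#
# The reference genome carries the Pachón alleles: lesions shared by the
# cave lineages are planted so that they appear as variants in the Surface
# alignment, and the Tinaja-specific lesion as a variant in the Tinaja
# alignment. Decoy lesions exercise each screen filter: one on an
# undersized scaffold, one within 3 bp of a splice boundary, one at 50%
# allele fraction, one under the depth floor.

FIXTURE_INTRON_BP <- 300L
FIXTURE_SCAFFOLD_BP <- 1100000L
FIXTURE_SMALL_SCAFFOLD_BP <- 500000L
FIXTURE_GENE_START <- 10001L

#' The packaged lesion specification
#'
#' Seven genes with their exon counts, mutation exon ordinals, cDNA
#' lengths, strands, and lesions given in carrier-allele cDNA coordinates
#' with derived-lineage polarity (an insertion is extra sequence in the
#' lineage that acquired it). Decoy genes (one per screen filter) are
#' appended unless `decoys = FALSE`.
#'
#' @param decoys Include the four filter-decoy genes.
#' @return List with data.frames `genes` and `lesions`.
#' @export
cavefish_lesion_spec <- function(decoys = TRUE) {
  genes <- read_tsv(system.file("extdata", "lesion_genes.tsv",
                                package = "cavescreen", mustWork = TRUE))
  lesions <- read_tsv(system.file("extdata", "lesion_table.tsv",
                                  package = "cavescreen", mustWork = TRUE))
  genes$scaffold <- paste0("scaffold_", genes$gene)
  genes$scaffold_bp <- FIXTURE_SCAFFOLD_BP
  genes$gene_start <- FIXTURE_GENE_START
  genes$depth_factor <- 1
  genes$carrier_fraction <- 1
  genes$boundary_margin <- 60L
  genes$decoy <- FALSE
  if (decoys) {
    dec_genes <- data.frame(
      gene = c("decoy_sc", "decoy_splice", "decoy_poly", "decoy_depth"),
      n_exons = 3L, mutation_exon = 2L, cdna_length = 900L, strand = "+",
      scaffold = c("scaffold_small", "scaffold_decoys", "scaffold_decoys",
                   "scaffold_decoys"),
      scaffold_bp = c(FIXTURE_SMALL_SCAFFOLD_BP, rep(FIXTURE_SCAFFOLD_BP, 3L)),
      gene_start = c(FIXTURE_GENE_START, FIXTURE_GENE_START, 200001L, 400001L),
      depth_factor = c(1, 1, 1, 0.5),
      carrier_fraction = c(1, 1, 0.5, 1),
      boundary_margin = c(60L, 2L, 60L, 60L),
      decoy = TRUE,
      stringsAsFactors = FALSE)
    dec_lesions <- data.frame(
      gene = dec_genes$gene, kind = "insertion",
      carrier_start = 450L, carrier_end = 452L, sequence = "CTA",
      variant_pop = "Surface", stringsAsFactors = FALSE)
    genes <- rbind(genes, dec_genes)
    lesions <- rbind(lesions, dec_lesions)
  }
  list(genes = genes, lesions = lesions)
}

# carrier-allele lesions -> observed events in reference-cDNA space.
# Reference carries the derived (cave) allele whenever Surface is the
# variant population; otherwise (wdr1-type) the reference carries the
# surface-like allele. delta tracks (variant-allele coord) - (ref coord).
observed_from_carrier <- function(lesions) {
  out <- list()
  for (g in unique(lesions$gene)) {
    lg <- lesions[lesions$gene == g, , drop = FALSE]
    lg <- lg[order(lg$carrier_start), , drop = FALSE]
    surface_variant <- "Surface" %in% unlist(strsplit(lg$variant_pop, ","))
    delta <- 0L
    for (i in seq_len(nrow(lg))) {
      len <- nchar(lg$sequence[i])
      ref_carries <- (lg$kind[i] == "insertion") == surface_variant
      if (ref_carries) {
        obs_kind <- "deletion"
        ref_start <- lg$carrier_start[i]       # carrier == reference
        ref_end <- lg$carrier_end[i]
        delta <- delta - len
      } else {
        obs_kind <- "insertion"
        ref_start <- lg$carrier_start[i] - delta - 1L   # anchor base
        ref_end <- ref_start + 1L                        # right flank
        delta <- delta + len
      }
      out[[length(out) + 1L]] <- data.frame(
        gene = g, lesion_id = paste0(g, ":", i),
        kind = lg$kind[i], carrier_start = lg$carrier_start[i],
        carrier_end = lg$carrier_end[i], sequence = toupper(lg$sequence[i]),
        variant_pop = lg$variant_pop[i],
        obs_kind = obs_kind, ref_start = ref_start, ref_end = ref_end,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# deterministic exon layout in cDNA space: exon `m` contains the lesion
# window with `margin` bp of flank; remaining length is split evenly
exon_layout <- function(cdna_length, n_exons, m, lesion_lo, lesion_hi,
                        margin = 60L) {
  N <- as.integer(cdna_length); K <- as.integer(n_exons)
  lo <- max(1L, lesion_lo - margin)
  hi <- min(N, lesion_hi + margin)
  if (m == 1L) lo <- 1L
  if (m == K) hi <- N
  pre <- lo - 1L
  post <- N - hi
  if (pre < m - 1L || post < K - m) {
    stop("cannot fit ", K, " exons around lesion window [", lesion_lo, ", ",
         lesion_hi, "] in a ", N, " bp transcript")
  }
  widths <- integer(K)
  if (m > 1L) widths[seq_len(m - 1L)] <- diff(round(seq(0L, pre, length.out = m)))
  widths[m] <- hi - lo + 1L
  if (m < K) widths[(m + 1L):K] <- diff(round(seq(0L, post, length.out = K - m + 1L)))
  stopifnot(sum(widths) == N, all(widths >= 1L))
  widths
}

# genomic exon coordinates for a transcript laid down at gene_start with
# constant introns; exons returned in transcript order
exon_genomic_coords <- function(widths, strand, gene_start) {
  K <- length(widths)
  w_genomic <- if (strand == "+") widths else rev(widths)  # genomic order
  starts <- integer(K); ends <- integer(K)
  pos <- gene_start
  for (i in seq_len(K)) {
    starts[i] <- pos
    ends[i] <- pos + w_genomic[i] - 1L
    pos <- ends[i] + FIXTURE_INTRON_BP + 1L
  }
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  list(starts = starts, ends = ends)
}

# reference transcript sequence with planted lesions and shift-proof flanks
build_ref_cdna <- function(N, obs) {
  s <- random_dna(N)
  for (i in seq_len(nrow(obs))) {
    seq_i <- obs$sequence[i]
    len <- nchar(seq_i)
    if (obs$obs_kind[i] == "deletion") {
      d <- obs$ref_start[i]; e <- obs$ref_end[i]
      substr(s, d, e) <- seq_i
      if (d > 1L) substr(s, d - 1L, d - 1L) <-
          other_base(c(substr(seq_i, len, len)))
      if (e < N) substr(s, e + 1L, e + 1L) <-
          other_base(c(substr(seq_i, 1L, 1L)))
    } else {
      a <- obs$ref_start[i]
      substr(s, a, a) <- other_base(substr(seq_i, len, len))
      if (a < N) substr(s, a + 1L, a + 1L) <-
          other_base(substr(seq_i, 1L, 1L))
    }
  }
  s
}

# transcript-orientation alignment blueprint of an allele against the
# reference gene: rows op (M/I/D/N), len, allele_start, ref_start
allele_blueprint <- function(model, obs_events, variant) {
  N <- model$cdna_length
  rows <- list()
  push <- function(op, len, allele_start, ref_start) {
    rows[[length(rows) + 1L]] <<- data.frame(
      op = op, len = as.integer(len),
      allele_start = as.integer(allele_start),
      ref_start = as.integer(ref_start), stringsAsFactors = FALSE)
  }
  ev <- if (variant && nrow(obs_events) > 0L) {
    obs_events[order(obs_events$ref_start), , drop = FALSE]
  } else obs_events[0L, , drop = FALSE]
  rpos <- 1L; apos <- 1L
  for (i in seq_len(nrow(ev))) {
    len <- nchar(ev$sequence[i])
    if (ev$obs_kind[i] == "deletion") {
      d <- ev$ref_start[i]
      if (d > rpos) { push("M", d - rpos, apos, rpos); apos <- apos + (d - rpos) }
      push("D", len, NA, d)
      rpos <- d + len
    } else {
      a <- ev$ref_start[i]
      if (a + 1L > rpos) { push("M", a - rpos + 1L, apos, rpos); apos <- apos + (a - rpos + 1L) }
      push("I", len, apos, NA)
      apos <- apos + len
      rpos <- a + 1L
    }
  }
  if (rpos <= N) push("M", N - rpos + 1L, apos, rpos)
  bp <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # split reference-consuming ops at exon boundaries, bridging with N ops
  cum <- model$cum_end
  out <- list()
  for (i in seq_len(nrow(bp))) {
    r <- bp[i, ]
    if (!r$op %in% c("M", "D")) { out[[length(out) + 1L]] <- r; next }
    rs <- r$ref_start; re <- rs + r$len - 1L
    as <- r$allele_start
    while (TRUE) {
      exon_i <- findInterval(rs - 1L, c(0L, cum))
      exon_end <- cum[exon_i]
      seg_end <- min(re, exon_end)
      seg <- r
      seg$ref_start <- rs; seg$len <- seg_end - rs + 1L
      seg$allele_start <- if (r$op == "M") as else NA_integer_
      out[[length(out) + 1L]] <- seg
      if (r$op == "M") as <- as + seg$len
      if (seg_end == re) break
      out[[length(out) + 1L]] <- data.frame(
        op = "N", len = FIXTURE_INTRON_BP, allele_start = NA_integer_,
        ref_start = seg_end + 1L, stringsAsFactors = FALSE)
      rs <- seg_end + 1L
    }
  }
  bp <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  # allele position immediately left of each zero-allele-width op, used to
  # decide whether a read spans it
  ap <- 0L
  bp$allele_before <- NA_integer_
  for (i in seq_len(nrow(bp))) {
    if (bp$op[i] %in% c("M", "I")) {
      ap <- bp$allele_start[i] + bp$len[i] - 1L
    } else {
      bp$allele_before[i] <- ap
    }
  }
  bp
}

# one read's SAM fields from a blueprint window [s, e] (allele coords)
read_from_blueprint <- function(bp, model, s, e) {
  ops <- character(0); lens <- integer(0)
  ref_lo <- NA_integer_; ref_hi <- NA_integer_
  for (i in seq_len(nrow(bp))) {
    op <- bp$op[i]
    if (op %in% c("M", "I")) {
      as <- bp$allele_start[i]; ae <- as + bp$len[i] - 1L
      lo <- max(as, s); hi <- min(ae, e)
      if (lo > hi) next
      len <- hi - lo + 1L
      if (op == "M") {
        r1 <- bp$ref_start[i] + (lo - as)
        if (is.na(ref_lo)) ref_lo <- r1
        ref_hi <- r1 + len - 1L
      }
      ops <- c(ops, op); lens <- c(lens, len)
    } else {
      ab <- bp$allele_before[i]
      if (s <= ab && e >= ab + 1L) {
        ops <- c(ops, op); lens <- c(lens, bp$len[i])
      }
    }
  }
  # terminal insertions have no anchor: emit as soft clips
  if (length(ops) && ops[1L] == "I") ops[1L] <- "S"
  if (length(ops) && ops[length(ops)] == "I") ops[length(ops)] <- "S"
  if (is.na(ref_lo)) return(NULL)   # read entirely inside an insertion
  if (model$strand == "-") { ops <- rev(ops); lens <- rev(lens) }
  gpos <- if (model$strand == "+") cdna_to_genomic(model, ref_lo)
          else cdna_to_genomic(model, ref_hi)
  list(pos = gpos, cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate spliced reads for one gene and one allele
#'
#' Reads of fixed length tile the allele transcript in `depth` deterministic
#' passes (per-pass phase shift, step = read length), so mean spanning depth
#' away from the transcript ends equals `depth`. Alignments are emitted
#' against the genome with N operators across introns and I/D operators at
#' the planted lesions; substitution errors never touch the CIGAR.
#'
#' @param model [gene_model()] of the gene.
#' @param allele_seq The allele's cDNA sequence.
#' @param obs_events data.frame of observed events in reference-cDNA space
#'   (zero rows for the reference allele).
#' @param variant Does this allele carry the events?
#' @param depth Target spanning depth (passes), >= 1.
#' @param read_length Read length in bp; must not exceed the transcript.
#' @param error_rate Per-base substitution probability in [0, 0.25).
#' @param population Population label (used in read names).
#' @param pass_offset Integer added to pass numbers in read names, so mixed
#'   allele pools keep unique names.
#' @return List with `sam` (data.frame of SAM fields) and `truth`
#'   (data.frame read_id x lesion_id carried).
#' @export
simulate_reads <- function(model, allele_seq, obs_events, variant, depth,
                           read_length = 100L, error_rate = 0,
                           population = "pop", pass_offset = 0L) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must be in [0, 0.25)")
  L <- nchar(allele_seq)
  if (read_length > L) {
    stop("read_length (", read_length, ") exceeds transcript length (", L, ")")
  }
  bp <- allele_blueprint(model, obs_events, variant)
  # lesion spans in allele coordinates, for the truth map
  truth_spans <- NULL
  if (variant && nrow(obs_events) > 0L) {
    ts <- list()
    ins_rows <- which(bp$op == "I")
    del_rows <- which(bp$op == "D")
    ev <- obs_events[order(obs_events$ref_start), , drop = FALSE]
    ii <- 1L; di <- 1L
    for (i in seq_len(nrow(ev))) {
      if (ev$obs_kind[i] == "insertion") {
        r <- ins_rows[ii]; ii <- ii + 1L
        ts[[i]] <- data.frame(lesion_id = ev$lesion_id[i],
                              span_lo = bp$allele_start[r] - 1L,
                              span_hi = bp$allele_start[r] + bp$len[r])
      } else {
        r <- del_rows[di]; di <- di + 1L
        ts[[i]] <- data.frame(lesion_id = ev$lesion_id[i],
                              span_lo = bp$allele_before[r],
                              span_hi = bp$allele_before[r] + 1L)
      }
    }
    truth_spans <- do.call(rbind, ts)
  }
  starts <- integer(0); passes <- integer(0)
  for (k in seq_len(depth)) {
    phase <- ((k - 1L) * read_length) %/% depth
    st <- seq.int(1L + phase, L - read_length + 1L, by = read_length)
    tail_start <- L - read_length + 1L
    if (st[length(st)] < tail_start) st <- c(st, tail_start)
    starts <- c(starts, st)
    passes <- c(passes, rep(k + pass_offset, length(st)))
  }
  n <- length(starts)
  qname <- sprintf("%s_%s_p%03d_s%06d", model$gene_name, population,
                   passes, starts)
  seqs <- substring(allele_seq, starts, starts + read_length - 1L)
  if (error_rate > 0) {
    chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                    nrow = n, byrow = TRUE)
    mask <- matrix(stats::runif(n * read_length) < error_rate, nrow = n)
    if (any(mask)) {
      repl <- vapply(chars[mask], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      chars[mask] <- repl
      seqs <- apply(chars, 1L, paste, collapse = "")
    }
  }
  aln <- lapply(seq_len(n), function(i)
    read_from_blueprint(bp, model, starts[i], starts[i] + read_length - 1L))
  keep <- !vapply(aln, is.null, TRUE)
  aln <- aln[keep]
  minus <- model$strand == "-"
  sam <- data.frame(
    qname = qname[keep],
    flag = if (minus) 16L else 0L,
    rname = model$scaffold,
    pos = vapply(aln, `[[`, 0L, "pos"),
    mapq = 60L,
    cigar = vapply(aln, `[[`, "", "cigar"),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = if (minus) revcomp(seqs[keep]) else seqs[keep],
    qual = strrep("I", read_length),
    stringsAsFactors = FALSE)
  truth <- data.frame(read_id = character(0), lesion_id = character(0))
  if (!is.null(truth_spans)) {
    e <- starts + read_length - 1L
    tr <- list()
    for (i in seq_len(nrow(truth_spans))) {
      carry <- keep & starts <= truth_spans$span_lo[i] & e >= truth_spans$span_hi[i]
      if (any(carry)) {
        tr[[i]] <- data.frame(read_id = qname[carry],
                              lesion_id = truth_spans$lesion_id[i],
                              stringsAsFactors = FALSE)
      }
    }
    if (length(tr)) truth <- do.call(rbind, c(tr, list(make.row.names = FALSE)))
  }
  list(sam = sam, truth = truth)
}

write_sam <- function(sam, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   BiocGenerics::width(genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                  sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq, sam$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# spot-check that M segments of written alignments reproduce the reference
validate_sam <- function(sam, genome, n_check = 200L) {
  idx <- if (nrow(sam) > n_check) {
    round(seq(1L, nrow(sam), length.out = n_check))
  } else seq_len(nrow(sam))
  ops <- parse_cigar_ops(sam$cigar[idx], sam$pos[idx])
  mm <- ops[ops$op %in% c("M", "=", "X"), , drop = FALSE]
  for (j in seq_len(nrow(mm))) {
    i <- idx[mm$read_i[j]]
    ref <- genome_slice(genome, sam$rname[i], mm$ref_start[j],
                        mm$ref_start[j] + mm$len[j] - 1L)
    got <- substr(sam$seq[i], mm$query_start[j],
                  mm$query_start[j] + mm$len[j] - 1L)
    if (ref != got) {
      stop("SAM self-check failed for read ", sam$qname[i],
           " at ", sam$rname[i], ":", mm$ref_start[j])
    }
  }
  invisible(TRUE)
}

#' Build the complete synthetic fixture
#'
#' Generates the toy genome, gene models (GFF3), per-population spliced
#' alignments (SAM), allele and outgroup FASTAs, QTL marker fixture and
#' truth tables, all under `outdir`. Byte-identical for identical
#' `(spec, seed, parameters)`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param depth Target spanning read depth per population.
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution error probability.
#' @param spec Lesion specification, as from [cavefish_lesion_spec()].
#' @param populations Population labels to simulate.
#' @param outgroup_divergence Substitution rate applied to the ancestral
#'   allele outside the lesion windows to emulate the outgroup ortholog.
#' @return List with file paths (`genome_fasta`, `gff3`, `sam` per
#'   population, `outgroup_fasta`, `domains_tsv`, `markers_tsv`), loaded
#'   objects (`genome`, `models`), the observed-event table (`events`),
#'   truth tables (`truth`, `read_truth`), marker expectations and the
#'   scaffold placement map.
#' @export
build_fixture <- function(outdir = tempfile("fixture"), seed = 1L,
                          depth = 60L, read_length = 100L, error_rate = 0,
                          spec = cavefish_lesion_spec(),
                          populations = c("Surface", "Pachon", "Tinaja"),
                          outgroup_divergence = 0.02) {
  set.seed(as.integer(seed))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genes <- spec$genes
  obs_all <- observed_from_carrier(spec$lesions)

  # sanity: lesion intervals must fit their transcripts
  for (i in seq_len(nrow(obs_all))) {
    N <- genes$cdna_length[genes$gene == obs_all$gene[i]]
    if (obs_all$ref_end[i] > N || obs_all$ref_start[i] < 1L) {
      stop("lesion ", obs_all$lesion_id[i], " exceeds the ", N,
           " bp transcript of ", obs_all$gene[i])
    }
  }

  # gene models + reference transcripts
  models <- list()
  ref_cdna <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene[i]
    obs <- obs_all[obs_all$gene == g, , drop = FALSE]
    lo <- min(obs$ref_start); hi <- max(obs$ref_end)
    widths <- exon_layout(genes$cdna_length[i], genes$n_exons[i],
                          genes$mutation_exon[i], lo, hi,
                          margin = genes$boundary_margin[i])
    coords <- exon_genomic_coords(widths, genes$strand[i], genes$gene_start[i])
    models[[g]] <- gene_model(paste0("gene:", g), g, genes$scaffold[i],
                              genes$strand[i], coords$starts, coords$ends)
    ref_cdna[[g]] <- build_ref_cdna(genes$cdna_length[i], obs)
  }

  # scaffolds with embedded exons
  scafs <- unique(genes[, c("scaffold", "scaffold_bp")])
  seqs <- character(nrow(scafs))
  names(seqs) <- scafs$scaffold
  for (i in seq_len(nrow(scafs))) seqs[i] <- random_dna(scafs$scaffold_bp[i])
  for (g in names(models)) {
    m <- models[[g]]
    s <- seqs[[m$scaffold]]
    for (j in seq_len(nrow(m$exons))) {
      sp <- exon_cdna_span(m, j)
      chunk <- substr(ref_cdna[[g]], sp[1L], sp[2L])
      if (m$strand == "-") chunk <- revcomp(chunk)
      substr(s, m$exons$genomic_start[j], m$exons$genomic_end[j]) <- chunk
    }
    seqs[[m$scaffold]] <- s
  }
  genome <- Biostrings::DNAStringSet(seqs)

  genome_fasta <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_fasta, width = 80L)
  gff3 <- file.path(outdir, "genes.gff3")
  write_fixture_gff3(models, gff3)

  # allele FASTAs per population and read simulation
  sam_paths <- character(0)
  read_truth <- list()
  allele_fastas <- character(0)
  for (pop in populations) {
    sam_rows <- list()
    alleles <- character(0)
    for (i in seq_len(nrow(genes))) {
      g <- genes$gene[i]
      m <- models[[g]]
      obs <- obs_all[obs_all$gene == g, , drop = FALSE]
      is_variant_pop <- pop %in% unlist(strsplit(obs$variant_pop, ","))
      var_seq <- apply_events_to_window(ref_cdna[[g]], 1L, data.frame(
        kind = obs$obs_kind, ref_start = obs$ref_start,
        sequence = obs$sequence, stringsAsFactors = FALSE))
      alleles[[g]] <- if (is_variant_pop) var_seq else ref_cdna[[g]]
      passes <- max(1L, as.integer(round(depth * genes$depth_factor[i])))
      frac <- if (is_variant_pop) genes$carrier_fraction[i] else 0
      n_var <- as.integer(round(passes * frac))
      if (n_var > 0L) {
        r <- simulate_reads(m, var_seq, obs, TRUE, n_var, read_length,
                            error_rate, pop)
        sam_rows[[length(sam_rows) + 1L]] <- r$sam
        if (nrow(r$truth)) {
          r$truth$population <- pop
          read_truth[[length(read_truth) + 1L]] <- r$truth
        }
      }
      if (passes - n_var > 0L) {
        r <- simulate_reads(m, ref_cdna[[g]], obs, FALSE, passes - n_var,
                            read_length, error_rate, pop, pass_offset = n_var)
        sam_rows[[length(sam_rows) + 1L]] <- r$sam
      }
    }
    sam <- do.call(rbind, c(sam_rows, list(make.row.names = FALSE)))
    path <- file.path(outdir, paste0(pop, ".sam"))
    write_sam(sam, genome, path)
    if (error_rate == 0) validate_sam(sam, genome)
    sam_paths[[pop]] <- path
    af <- file.path(outdir, paste0("alleles_", pop, ".fa"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(alleles)),
                                af, width = 80L)
    allele_fastas[[pop]] <- af
  }

  # outgroup: ancestral allele (surface) with divergence outside lesions
  real_genes <- genes$gene[!genes$decoy]
  outg <- character(0)
  for (g in real_genes) {
    obs <- obs_all[obs_all$gene == g, , drop = FALSE]
    surface_variant <- "Surface" %in% obs$variant_pop
    anc <- if (surface_variant) {
      apply_events_to_window(ref_cdna[[g]], 1L, data.frame(
        kind = obs$obs_kind, ref_start = obs$ref_start,
        sequence = obs$sequence, stringsAsFactors = FALSE))
    } else ref_cdna[[g]]
    protect <- rep(FALSE, nchar(anc))
    for (i in seq_len(nrow(obs))) {
      lo <- max(1L, obs$ref_start[i] - 110L)
      hi <- min(nchar(anc), obs$ref_end[i] + 110L)
      protect[lo:hi] <- TRUE
    }
    mut <- which(stats::runif(nchar(anc)) < outgroup_divergence & !protect)
    if (length(mut)) {
      ch <- strsplit(anc, "", fixed = TRUE)[[1L]]
      ch[mut] <- vapply(ch[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
      anc <- paste(ch, collapse = "")
    }
    outg[[g]] <- anc
  }
  outgroup_fasta <- file.path(outdir, "outgroup.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(outg)),
                              outgroup_fasta, width = 80L)

  # truth table per lesion
  truth <- lesion_truth_table(genes, obs_all, models, genome)
  write_tsv(truth, file.path(outdir, "truth_lesions.tsv"))
  read_truth <- if (length(read_truth)) {
    do.call(rbind, c(read_truth, list(make.row.names = FALSE)))
  } else data.frame(read_id = character(0), lesion_id = character(0),
                    population = character(0))
  write_tsv(read_truth, file.path(outdir, "truth_reads.tsv"))

  # packaged domain table + marker fixture
  domains_tsv <- file.path(outdir, "domains.tsv")
  file.copy(system.file("extdata", "protein_domains.tsv",
                        package = "cavescreen", mustWork = TRUE),
            domains_tsv, overwrite = TRUE)
  mk <- NULL
  markers_tsv <- NULL
  if (all(c("ghrb", "mia3", "wdr1", "plg") %in% names(models))) {
    mk <- make_marker_fixture(models, genes)
    markers_tsv <- file.path(outdir, "markers.tsv")
    write_tsv(mk$markers, markers_tsv)
  }

  list(outdir = outdir, seed = seed, depth = depth,
       read_length = read_length, error_rate = error_rate,
       genome_fasta = genome_fasta, gff3 = gff3, sam = sam_paths,
       allele_fastas = allele_fastas, outgroup_fasta = outgroup_fasta,
       domains_tsv = domains_tsv, markers_tsv = markers_tsv,
       genome = genome, models = models, spec = spec, events = obs_all,
       truth = truth, read_truth = read_truth,
       markers = mk$markers, marker_expected = mk$expected,
       scaffold_map = mk$scaffold_map)
}

# expected outcome per planted lesion
lesion_truth_table <- function(genes, obs_all, models, genome) {
  rows <- list()
  for (i in seq_len(nrow(obs_all))) {
    o <- obs_all[i, ]
    g <- o$gene
    m <- models[[g]]
    gi <- which(genes$gene == g)
    len <- nchar(o$sequence)
    if (o$obs_kind == "deletion") {
      gp <- sort(cdna_to_genomic(m, c(o$ref_start, o$ref_end)))
      gpos <- gp[1L]
    } else {
      gp <- sort(cdna_to_genomic(m, c(o$ref_start, o$ref_start + 1L)))
      gpos <- gp[1L]
    }
    seq_genomic <- if (m$strand == "-") revcomp(o$sequence) else o$sequence
    fail <- ""
    if (genes$scaffold_bp[gi] < 1e6) fail <- "scaffold"
    else if (genes$depth_factor[gi] < 1) fail <- "depth"
    else if (genes$carrier_fraction[gi] < 0.98) fail <- "genotype"
    else if (genes$boundary_margin[gi] < 10) fail <- "exonic"
    vpops <- unlist(strsplit(o$variant_pop, ","))
    surface_variant <- "Surface" %in% vpops
    expected_share <- if (!genes$decoy[gi]) {
      if (surface_variant || length(vpops) > 1L) "shared-cave"
      else paste0("single-cave(", vpops, ")")
    } else NA_character_
    final_kind <- o$kind   # derived-lineage polarity as specified
    rows[[i]] <- data.frame(
      gene = g, lesion_id = o$lesion_id,
      obs_kind = o$obs_kind, ref_cdna_start = o$ref_start,
      ref_cdna_end = if (o$obs_kind == "deletion") o$ref_end else o$ref_start + 1L,
      carrier_start = o$carrier_start, carrier_end = o$carrier_end,
      sequence = o$sequence, scaffold = m$scaffold, genomic_pos = gpos,
      sequence_genomic = seq_genomic,
      variant_pop = o$variant_pop,
      expect_survive = !genes$decoy[gi],
      expect_fail_filter = fail,
      expect_sharing = expected_share,
      expect_frame = if (len %% 3L == 0L) "in-frame" else "frameshift",
      expect_name = name_mutation(g, lesion(final_kind, o$carrier_start,
                                            o$carrier_end, o$sequence)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' QTL marker fixture with planted distances
#'
#' Places markers at recorded offsets from the fixture gene spans: one
#' inside a gene span (distance 0), a near and a far marker on one
#' chromosome, one far marker on another, and one on the undersized decoy
#' scaffold (different chromosome for every main gene). The plg scaffold is
#' omitted from the placement map, emulating a gene unplaced in the
#' assembly.
#'
#' @param models Named list of fixture [gene_model()]s.
#' @param genes Gene table of the fixture spec.
#' @return List with `markers` (loadable marker table), `expected`
#'   (gene/marker/distance truth) and `scaffold_map`.
#' @export
make_marker_fixture <- function(models, genes) {
  sp <- function(g) gene_span(models[[g]])
  markers <- data.frame(
    marker = c("129b", "203f", "218d", "229a", "dm1"),
    trait = c("jaw morphology", "eye morphology", "body morphology",
              "body morphology", "pigmentation"),
    chrom = c(models[["ghrb"]]$scaffold, models[["mia3"]]$scaffold,
              models[["mia3"]]$scaffold, models[["wdr1"]]$scaffold,
              "scaffold_small"),
    pos = c(sp("ghrb")[1L] + 100L,
            sp("mia3")[2L] + 600000L,
            sp("mia3")[2L] + 750000L,
            sp("wdr1")[2L] + 290000L,
            100L),
    source = "fixture",
    stringsAsFactors = FALSE)
  expected <- data.frame(
    gene = c("ghrb", "mia3", "mia3", "wdr1"),
    marker = c("129b", "203f", "218d", "229a"),
    distance = c(0, 600000, 750000, 290000),
    stringsAsFactors = FALSE)
  placed <- setdiff(unique(genes$scaffold), models[["plg"]]$scaffold)
  scaffold_map <- stats::setNames(placed, placed)
  list(markers = markers, expected = expected, scaffold_map = scaffold_map)
}

write_fixture_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (g in names(models)) {
    m <- models[[g]]
    spn <- gene_span(m)
    lines <- c(lines,
      sprintf("%s\tcavescreen\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s",
              m$scaffold, spn[1L], spn[2L], m$strand, g, g),
      sprintf("%s\tcavescreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=tr:%s;Parent=gene:%s",
              m$scaffold, spn[1L], spn[2L], m$strand, g, g))
    ex <- m$exons[order(m$exons$genomic_start), , drop = FALSE]
    lines <- c(lines,
      sprintf("%s\tcavescreen\texon\t%d\t%d\t.\t%s\t.\tID=exon:%s:%d;Parent=tr:%s",
              m$scaffold, ex$genomic_start, ex$genomic_end, m$strand,
              g, ex$ordinal, g))
  }
  writeLines(lines, path)
  invisible(path)
}
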