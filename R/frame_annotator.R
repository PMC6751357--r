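# Frame impact classification, cDNA -> protein mapping, mutation naming and
# protein-domain intersection.
#
# A lesion lives in cDNA space with 1-based closed coordinates. Insertions
# are numbered by the positions the inserted bases occupy in the cDNA of the
# insertion-bearing allele; deletions by the positions of the deleted bases
# in the allele that carries them. The signed length is +len for insertions
# and -len for deletions, so the running sum mod 3 is the reading-frame
# offset downstream of each lesion.

#' Construct a lesion
#'
#' @param kind `"insertion"` or `"deletion"`.
#' @param cdna_start,cdna_end 1-based inclusive cDNA interval of the
#'   inserted/deleted bases (in the carrier allele's cDNA).
#' @param sequence Inserted/deleted bases (cDNA orientation).
#' @return Object of class `lesion`.
#' @export
lesion <- function(kind, cdna_start, cdna_end, sequence) {
  kind <- match.arg(kind, c("insertion", "deletion"))
  cdna_start <- as.integer(cdna_start)
  cdna_end <- as.integer(cdna_end)
  sequence <- toupper(sequence)
  len <- cdna_end - cdna_start + 1L
  if (len < 1L) stop("lesion interval is empty")
  if (nchar(sequence) != len) {
    stop("lesion sequence length (", nchar(sequence),
         ") does not match interval length (", len, ")")
  }
  structure(list(kind = kind, cdna_start = cdna_start, cdna_end = cdna_end,
                 sequence = sequence,
                 signed_length = if (kind == "insertion") len else -len),
            class = "lesion")
}

#' Classify the reading-frame impact of a single lesion
#'
#' A lesion whose length is divisible by 3 leaves the downstream reading
#' frame intact; any other length shifts it.
#'
#' @param l A [lesion()].
#' @return `"in-frame"` or `"frameshift"`.
#' @export
classify_frame <- function(l) {
  len <- abs(l$signed_length)
  if (len == 0L) stop("zero-length lesion")
  if (len %% 3L == 0L) "in-frame" else "frameshift"
}

#' Combined frame effect of several lesions on one transcript
#'
#' Walks the lesions in cDNA order, accumulating the signed length mod 3.
#' A compound pair such as a +1 insertion followed 4 bp later by a -1
#' deletion shifts the frame only in the short interval between them; the
#' position of the lesion at which the offset first returns to 0 after
#' having been nonzero is reported as `restoration_pos`.
#'
#' @param lesions List of [lesion()]s, non-overlapping, on one transcript.
#' @return List with `classes` (per-lesion frame class), `track`
#'   (data.frame of cdna_start and cumulative offset mod 3 after each
#'   lesion), `net_offset` (integer mod 3) and `restoration_pos` (cDNA bp
#'   or `NA`).
#' @export
compound_frame <- function(lesions) {
  if (length(lesions) == 0L) {
    return(list(classes = character(0),
                track = data.frame(cdna_pos = integer(0), offset = integer(0)),
                net_offset = 0L, restoration_pos = NA_integer_))
  }
  starts <- vapply(lesions, `[[`, 0L, "cdna_start")
  ends <- vapply(lesions, `[[`, 0L, "cdna_end")
  o <- order(starts)
  lesions <- lesions[o]; starts <- starts[o]; ends <- ends[o]
  if (length(lesions) > 1L && any(starts[-1L] <= ends[-length(ends)])) {
    stop("overlapping lesions")
  }
  signed <- vapply(lesions, `[[`, 0L, "signed_length")
  offs <- cumsum(signed) %% 3L
  restoration <- NA_integer_
  prev <- 0L
  for (i in seq_along(offs)) {
    if (prev != 0L && offs[i] == 0L) { restoration <- starts[i]; break }
    prev <- offs[i]
  }
  list(classes = vapply(lesions, classify_frame, ""),
       track = data.frame(cdna_pos = starts, offset = offs),
       net_offset = offs[length(offs)],
       restoration_pos = restoration)
}

#' Map a cDNA position to a protein residue index
#'
#' `residue = ceiling((cpos - cds_offset) / 3)` with `cds_offset` the
#' 0-based cDNA offset of the first CDS base.
#'
#' @param cpos 1-based cDNA position(s).
#' @param cds_offset 0-based CDS start offset (default 0).
#' @return Integer residue index/indices (1-based).
#' @export
cdna_to_protein <- function(cpos, cds_offset = 0L) {
  cpos <- as.integer(cpos)
  if (any(cpos <= cds_offset)) {
    stop("cDNA position ", paste(cpos[cpos <= cds_offset], collapse = ","),
         " lies 5' of the CDS (cds_offset ", cds_offset, ")")
  }
  as.integer(ceiling((cpos - cds_offset) / 3))
}

#' Residues gained by an in-frame insertion (or lost by a deletion)
#'
#' @param l An in-frame [lesion()].
#' @return Integer residue count, `abs(signed_length) / 3`.
#' @export
residue_gain <- function(l) {
  if (classify_frame(l) != "in-frame") {
    stop("residue_gain is defined only for in-frame lesions")
  }
  abs(l$signed_length) %/% 3L
}

#' Name a mutation
#'
#' Produces `gene^Ins<a>-<b>` / `gene^Δ<a>-<b>` style names (en dash,
#' Greek delta); single-position lesions omit the range. `ascii = TRUE`
#' substitutes `del` for the delta and a hyphen for the en dash, for
#' file-safe output.
#'
#' @param gene_name Gene display name.
#' @param l A [lesion()].
#' @param ascii Use the ASCII alias.
#' @return A single string.
#' @export
name_mutation <- function(gene_name, l, ascii = FALSE) {
  op <- if (l$kind == "insertion") "Ins" else if (ascii) "del" else "Δ"
  dash <- if (ascii) "-" else "–"
  rng <- if (l$cdna_start == l$cdna_end) as.character(l$cdna_start) else
    paste0(l$cdna_start, dash, l$cdna_end)
  paste0(gene_name, "^", op, rng)
}

#' Parse a mutation name back into its parts
#'
#' Accepts both the Unicode and the ASCII alias form.
#'
#' @param name A string produced by [name_mutation()].
#' @return List with `gene`, `kind`, `cdna_start`, `cdna_end`.
#' @export
parse_mutation_name <- function(name) {
  m <- regmatches(name, regexec(
    "^(.+)\\^(Ins|Δ|del)([0-9]+)(?:[–-]([0-9]+))?$", name))[[1L]]
  if (length(m) == 0L) stop("unparseable mutation name: ", name)
  a <- as.integer(m[4L])
  b <- if (m[5L] == "") a else as.integer(m[5L])
  list(gene = m[2L],
       kind = if (m[3L] == "Ins") "insertion" else "deletion",
       cdna_start = a, cdna_end = b)
}

#' Load a protein domain table
#'
#' Tab-separated columns: `gene`, `domain_name`, `aa_start`, `aa_end`.
#'
#' @param path TSV file path.
#' @return data.frame of domain intervals.
#' @export
load_domains <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "domain_name", "aa_start", "aa_end")
  if (!all(need %in% names(df))) {
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  }
  df$aa_start <- as.integer(df$aa_start)
  df$aa_end <- as.integer(df$aa_end)
  if (any(df$aa_start > df$aa_end)) stop("domain with aa_start > aa_end")
  df
}

#' Intersect a residue interval with domain intervals
#'
#' Closed-interval intersection; touching a domain at a single residue
#' counts as impact.
#'
#' @param aa_start,aa_end 1-based residue interval.
#' @param domains data.frame as from [load_domains()] (already subset to
#'   the gene of interest, or carrying a `gene` column plus `gene` arg).
#' @param gene Optional gene name used to subset `domains`.
#' @return data.frame of impacted domain rows (possibly empty).
#' @export
domain_overlap <- function(aa_start, aa_end, domains, gene = NULL) {
  if (is.null(domains)) {
    domains <- data.frame(gene = character(0), domain_name = character(0),
                          aa_start = integer(0), aa_end = integer(0))
  }
  if (nrow(domains) == 0L) return(domains)
  if (!is.null(gene) && "gene" %in% names(domains)) {
    domains <- domains[domains$gene == gene, , drop = FALSE]
  }
  domains[domains$aa_start <= aa_end & domains$aa_end >= aa_start, , drop = FALSE]
}

#' Scan a mutated CDS for a premature stop codon
#'
#' Optional follow-up for frameshift lesions: translates the supplied
#' (already mutated) CDS from `cds_offset` and reports the residue index of
#' the first stop codon, or `NA` if none.
#'
#' @param cds_seq Nucleotide string of the mutated transcript.
#' @param cds_offset 0-based CDS start offset.
#' @return Integer residue index of the first stop, or `NA`.
#' @export
premature_stop <- function(cds_seq, cds_offset = 0L) {
  s <- toupper(substr(cds_seq, cds_offset + 1L, nchar(cds_seq)))
  n <- nchar(s) %/% 3L
  if (n == 0L) return(NA_integer_)
  codons <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(hit)) hit[1L] else NA_integer_
}

# ---- annotation of screened candidates --------------------------------------

# Carrier-allele coordinates for observed events on one transcript.
#
# `obs` rows are events as seen in reads aligned against the reference:
# an observed "deletion" removes reference-cDNA bases [ref_start, ref_end];
# an observed "insertion" adds `len` bases between reference-cDNA anchor
# `ref_start` and `ref_start + 1`. Deleted bases are carried by the
# reference allele, so their carrier coordinates are the reference
# coordinates. Inserted bases are carried by the variant allele, whose
# coordinates differ from reference coordinates by the cumulative signed
# length of upstream events.
carrier_coords <- function(obs) {
  obs <- obs[order(obs$ref_start), , drop = FALSE]
  delta <- 0L   # (variant-allele coord) - (reference coord), left of event
  cs <- ce <- integer(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    len <- nchar(obs$sequence[i])
    if (obs$kind[i] == "deletion") {
      cs[i] <- obs$ref_start[i]
      ce[i] <- obs$ref_start[i] + len - 1L
      delta <- delta - len
    } else {
      cs[i] <- obs$ref_start[i] + delta + 1L
      ce[i] <- cs[i] + len - 1L
      delta <- delta + len
    }
  }
  obs$carrier_start <- cs
  obs$carrier_end <- ce
  obs
}

#' Annotate screened candidate indels
#'
#' Groups candidates by gene, derives carrier-allele cDNA coordinates,
#' classifies single and compound frame impact, maps lesions to protein
#' residues, names them, and intersects with protein domains. Candidate
#' kinds/coordinates are "observed" (read vs reference); population
#' comparison may later re-express polarity against the ancestral allele.
#'
#' @param candidates data.frame from [run_screen()] (`$candidates`).
#' @param models Named list of [gene_model()]s.
#' @param domains Optional domain table ([load_domains()]); `NULL` yields
#'   empty impact lists with a notice.
#' @param config [screen_config()] (unused thresholds are ignored here).
#' @return List of class `annotated_indels` with data.frames `lesions`
#'   (one row per lesion) and `genes` (per-transcript compound summary).
#' @export
annotate_candidates <- function(candidates, models, domains = NULL,
                                config = screen_config()) {
  if (is.null(domains)) {
    message("no protein domain table supplied; impacted_domains will be empty")
  }
  if (nrow(candidates) == 0L) {
    return(structure(list(
      lesions = data.frame(gene = character(0)),
      genes = data.frame(gene = character(0))), class = "annotated_indels"))
  }
  les_rows <- list()
  gene_rows <- list()
  for (g in unique(candidates$gene_name)) {
    cand <- candidates[candidates$gene_name == g, , drop = FALSE]
    model <- models[[g]]
    if (is.null(model)) stop("no gene model for candidate gene ", g)
    minus <- model$strand == "-"
    # observed events in reference-cDNA space, collapsing duplicate loci
    # (the same variant seen from more than one population)
    key <- paste(cand$kind, cand$cdna_start, cand$cdna_end, cand$sequence)
    pops <- tapply(cand$population, key, function(p) paste(sort(unique(p)), collapse = ","))
    cand <- cand[!duplicated(key), , drop = FALSE]
    cand$populations <- as.character(pops[paste(cand$kind, cand$cdna_start,
                                                cand$cdna_end, cand$sequence)])
    seq_cdna <- ifelse(rep(minus, nrow(cand)), revcomp(cand$sequence), cand$sequence)
    obs <- data.frame(kind = cand$kind,
                      ref_start = cand$cdna_start,
                      ref_end = cand$cdna_end,
                      sequence = seq_cdna,
                      genomic_pos = cand$genomic_pos,
                      scaffold = cand$scaffold,
                      populations = cand$populations,
                      depth = cand$depth, alt_count = cand$alt_count,
                      allele_fraction = cand$allele_fraction,
                      stringsAsFactors = FALSE)
    obs <- carrier_coords(obs)
    lesions <- lapply(seq_len(nrow(obs)), function(i) {
      lesion(obs$kind[i], obs$carrier_start[i], obs$carrier_end[i], obs$sequence[i])
    })
    fr <- compound_frame(lesions)
    aa_start <- cdna_to_protein(obs$carrier_start, model$cds_offset)
    aa_end <- cdna_to_protein(obs$carrier_end, model$cds_offset)
    doms <- vapply(seq_len(nrow(obs)), function(i) {
      hit <- domain_overlap(aa_start[i], aa_end[i], domains, gene = g)
      if (nrow(hit) == 0L) "" else paste(hit$domain_name, collapse = ",")
    }, character(1))
    ordn <- t(vapply(obs$ref_start, function(cp) exon_of(model, cp), integer(2)))
    les_rows[[g]] <- data.frame(
      gene = g,
      scaffold = obs$scaffold,
      genomic_pos = obs$genomic_pos,
      kind = obs$kind,
      sequence = obs$sequence,
      ref_cdna_start = obs$ref_start,
      ref_cdna_end = obs$ref_end,
      carrier_start = obs$carrier_start,
      carrier_end = obs$carrier_end,
      frame_class = fr$classes,
      name = vapply(seq_along(lesions), function(i)
        name_mutation(g, lesions[[i]]), character(1)),
      name_ascii = vapply(seq_along(lesions), function(i)
        name_mutation(g, lesions[[i]], ascii = TRUE), character(1)),
      aa_start = aa_start,
      aa_end = aa_end,
      residues_gained = vapply(lesions, function(l)
        if (classify_frame(l) == "in-frame") residue_gain(l) else NA_integer_,
        integer(1)),
      impacted_domains = doms,
      exon_ordinal = ordn[, 1L],
      n_exons = ordn[, 2L],
      populations = obs$populations,
      depth = obs$depth,
      alt_count = obs$alt_count,
      allele_fraction = obs$allele_fraction,
      stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(
      gene = g,
      n_lesions = nrow(obs),
      cdna_length = model$cdna_length,
      strand = model$strand,
      net_offset = fr$net_offset,
      restoration_pos = fr$restoration_pos,
      frame_summary = if (all(fr$classes == "in-frame")) "in-frame"
        else if (fr$net_offset == 0L) "compound-restored" else "frameshift",
      names = paste(les_rows[[g]]$name, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  structure(list(lesions = do.call(rbind, c(les_rows, list(make.row.names = FALSE))),
                 genes = do.call(rbind, c(gene_rows, list(make.row.names = FALSE)))),
            class = "annotated_indels")
}
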