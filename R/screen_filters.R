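# The fixed-difference filter cascade: scaffold size, read depth, allele
# fraction ("percent genotype"), and exonic location away from splice
# boundaries. All thresholds are inclusive ("50 or more", "at least 1 Mb",
# "98-100%"). Every input site receives a full audit trace; survivors are
# sites passing every filter.

#' Screen configuration
#'
#' Defaults encode the published screen: scaffolds of at least 1 Mb, sites
#' with 50 or more spanning reads carrying the indel in 98-100% of them,
#' restricted to exonic sequence away from splice boundaries. The
#' exon-boundary margin has no published value; 10 bp is this package's
#' default and is reported in the audit log.
#'
#' @param min_scaffold_bp Minimum scaffold length (bp).
#' @param min_depth Minimum spanning-read depth.
#' @param min_allele_fraction Minimum indel allele fraction.
#' @param min_exon_boundary_bp Minimum cDNA distance to a splice boundary.
#' @param coding_only Restrict to annotated exonic sequence.
#' @param boundary_include_termini Treat transcript ends as boundaries.
#' @param surface_pop,cave_pops Population labels; the reference genome is
#'   assumed to carry the allele of the first cave population.
#' @param polarization_window cDNA bp of flank used around a lesion when
#'   aligning alleles to the outgroup.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(min_scaffold_bp = 1e6,
                          min_depth = 50,
                          min_allele_fraction = 0.98,
                          min_exon_boundary_bp = 10,
                          coding_only = TRUE,
                          boundary_include_termini = FALSE,
                          surface_pop = "Surface",
                          cave_pops = c("Pachon", "Tinaja"),
                          polarization_window = 60) {
  stopifnot(min_scaffold_bp >= 0, min_depth >= 0,
            min_allele_fraction >= 0, min_allele_fraction <= 1,
            min_exon_boundary_bp >= 0, polarization_window >= 0)
  structure(list(min_scaffold_bp = min_scaffold_bp,
                 min_depth = min_depth,
                 min_allele_fraction = min_allele_fraction,
                 min_exon_boundary_bp = min_exon_boundary_bp,
                 coding_only = coding_only,
                 boundary_include_termini = boundary_include_termini,
                 surface_pop = surface_pop,
                 cave_pops = cave_pops,
                 polarization_window = polarization_window),
            class = "screen_config")
}

#' Read a flat key = value configuration file
#'
#' Lines of `key = value` (TOML-style scalars; `#` comments allowed).
#' Unknown keys are rejected. Values are coerced to the type of the
#' corresponding [screen_config()] default; `cave_pops` takes a
#' comma-separated list.
#'
#' @param path Config file path.
#' @return A [screen_config()].
#' @export
read_screen_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- screen_config()
  args <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(kv) == 0L) stop("unparseable config line: ", ln)
    key <- kv[2L]; val <- gsub('^"|"$', "", trimws(kv[3L]))
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    proto <- defaults[[key]]
    args[[key]] <- if (is.logical(proto)) as.logical(val)
      else if (is.numeric(proto)) as.numeric(val)
      else if (key == "cave_pops") trimws(strsplit(val, ",")[[1L]])
      else val
  }
  do.call(screen_config, args)
}

#' Scaffold-size filter
#'
#' @param site One site row (list or 1-row data.frame) with `$scaffold`.
#' @param genome [load_genome()] result.
#' @param config [screen_config()].
#' @return List with `pass` and measured `value` (scaffold length).
#' @export
filter_scaffold <- function(site, genome, config = screen_config()) {
  len <- scaffold_length(genome, site$scaffold)
  list(pass = len >= config$min_scaffold_bp, value = len)
}

#' Depth filter
#'
#' @inheritParams filter_scaffold
#' @return List with `pass` and measured `value` (depth).
#' @export
filter_depth <- function(site, config = screen_config()) {
  list(pass = site$depth >= config$min_depth, value = site$depth)
}

#' Genotype (allele fraction) filter
#'
#' @inheritParams filter_scaffold
#' @return List with `pass` and measured `value` (allele fraction).
#' @export
filter_genotype <- function(site, config = screen_config()) {
  list(pass = site$allele_fraction >= config$min_allele_fraction,
       value = site$allele_fraction)
}

#' Exonic-location filter
#'
#' Passes when the whole event lies inside one exon of some gene model and
#' its cDNA distance to the nearest splice boundary is at least the
#' configured margin. On pass the containing model and the cDNA interval of
#' the event (sorted transcript coordinates of its genomic footprint:
#' deleted bases, or the two bases flanking an insertion point) are
#' attached.
#'
#' @inheritParams filter_scaffold
#' @param models Named list of [gene_model()]s.
#' @return List with `pass`, `value` (boundary distance; `NA` when not
#'   exonic), and on pass `gene_name`, `cdna_start`, `cdna_end`.
#' @export
filter_exonic <- function(site, models, config = screen_config()) {
  len <- nchar(site$sequence)
  gpos <- if (site$kind == "insertion") c(site$genomic_pos, site$genomic_pos + 1L)
          else c(site$genomic_pos, site$genomic_pos + len - 1L)
  for (model in models) {
    if (model$scaffold != site$scaffold) next
    cd <- genomic_to_cdna(model, gpos)
    if (anyNA(cd)) next
    cd <- sort(range(cd))
    # whole event inside one exon
    e1 <- exon_of(model, cd[1L])[1L]
    e2 <- exon_of(model, cd[2L])[1L]
    if (e1 != e2) next
    bd <- min(exon_boundary_distance(model, cd,
                                     include_termini = config$boundary_include_termini))
    return(list(pass = bd >= config$min_exon_boundary_bp, value = bd,
                gene_name = model$gene_name,
                cdna_start = cd[1L], cdna_end = cd[2L]))
  }
  list(pass = FALSE, value = NA_real_, gene_name = NA_character_,
       cdna_start = NA_integer_, cdna_end = NA_integer_)
}

#' Run the full filter cascade over a site table
#'
#' Filters are applied in screen order (scaffold, depth, genotype, exonic);
#' they are independent predicates, so order affects only the audit trace,
#' never the surviving set. Every input site appears in the audit log with
#' one row per filter.
#'
#' @param sites data.frame from [pileup_sites()] (possibly several
#'   populations concatenated).
#' @param genome [load_genome()] result.
#' @param models Named list of [gene_model()]s.
#' @param config [screen_config()].
#' @return List with `candidates` (surviving sites plus gene_name,
#'   cdna_start, cdna_end, boundary_bp) and `audit` (site key, filter,
#'   pass, value).
#' @export
run_screen <- function(sites, genome, models, config = screen_config()) {
  filters <- c("scaffold", "depth", "genotype", "exonic")
  n <- nrow(sites)
  audit <- vector("list", n)
  keep <- logical(n)
  gene_name <- character(n); cdna_start <- cdna_end <- integer(n)
  boundary <- numeric(n)
  for (i in seq_len(n)) {
    s <- sites[i, ]
    key <- paste(s$scaffold, s$genomic_pos, s$kind, s$sequence, s$population,
                 sep = ":")
    r1 <- filter_scaffold(s, genome, config)
    r2 <- filter_depth(s, config)
    r3 <- filter_genotype(s, config)
    r4 <- filter_exonic(s, models, config)
    audit[[i]] <- data.frame(
      site = key, filter = filters,
      pass = c(r1$pass, r2$pass, r3$pass, r4$pass),
      value = c(r1$value, r2$value, r3$value, r4$value),
      stringsAsFactors = FALSE)
    keep[i] <- r1$pass && r2$pass && r3$pass && r4$pass
    gene_name[i] <- r4$gene_name
    cdna_start[i] <- r4$cdna_start %||% NA_integer_
    cdna_end[i] <- r4$cdna_end %||% NA_integer_
    boundary[i] <- r4$value
  }
  cand <- sites
  cand$gene_name <- gene_name
  cand$cdna_start <- cdna_start
  cand$cdna_end <- cdna_end
  cand$boundary_bp <- boundary
  cand <- cand[keep, , drop = FALSE]
  rownames(cand) <- NULL
  audit_df <- if (n == 0L) {
    data.frame(site = character(0), filter = character(0),
               pass = logical(0), value = numeric(0))
  } else {
    do.call(rbind, c(audit, list(make.row.names = FALSE)))
  }
  list(candidates = cand, audit = audit_df)
}
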