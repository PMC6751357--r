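# Cross-population sharing classes and outgroup polarization.
#
# The reference genome carries the alleles of one morph (here the Pachón
# cave population), so a lesion shared by the cave lineages shows up as a
# variant in the *surface* alignment. Sharing classes are therefore
# expressed in morph space (which populations differ from which), not in
# variant-vs-reference space; both orientations are reported.

#' Per-population genotype state at a locus
#'
#' @param depth Spanning-read depth (0 allowed).
#' @param alt_count Reads carrying the variant.
#' @param config [screen_config()]; `min_depth` and `min_allele_fraction`
#'   are reused as the state thresholds.
#' @return One of `"variant-fixed"`, `"reference-fixed"`, `"polymorphic"`,
#'   `"low-coverage"`.
#' @export
genotype_state <- function(depth, alt_count, config = screen_config()) {
  stopifnot(depth >= 0, alt_count >= 0, alt_count <= max(depth, alt_count))
  if (depth < config$min_depth) return("low-coverage")
  f <- alt_count / depth
  if (f >= config$min_allele_fraction) "variant-fixed"
  else if (f <= 1 - config$min_allele_fraction) "reference-fixed"
  else "polymorphic"
}

#' Sharing class from per-population genotype states
#'
#' With three populations and a biallelic locus the informative patterns
#' are: the surface population differs from both caves (`shared-cave`; the
#' cave-shared allele equals the reference when the reference is a cave
#' genome), or exactly one cave differs from the other two
#' (`single-cave(<pop>)`). Any polymorphic or low-coverage member, or no
#' between-population difference at all, is `uninformative`.
#'
#' @param states Named character vector of [genotype_state()] values for
#'   all populations.
#' @param surface_pop,cave_pops Population labels.
#' @return A single class string.
#' @export
sharing_class <- function(states, surface_pop = "Surface",
                          cave_pops = c("Pachon", "Tinaja")) {
  pops <- c(surface_pop, cave_pops)
  if (!all(pops %in% names(states))) {
    stop("missing population label(s): ",
         paste(setdiff(pops, names(states)), collapse = ", "))
  }
  states <- states[pops]
  if (any(states %in% c("polymorphic", "low-coverage"))) return("uninformative")
  allele <- ifelse(states == "variant-fixed", "var", "ref")
  if (length(unique(allele)) == 1L) return("uninformative")
  surf <- allele[[surface_pop]]
  caves <- allele[cave_pops]
  if (length(unique(caves)) == 1L && unique(caves) != surf) return("shared-cave")
  odd <- cave_pops[caves != surf]
  if (length(odd) == 1L) return(paste0("single-cave(", odd, ")"))
  "uninformative"
}

#' Polarize two alleles against an outgroup sequence
#'
#' Globally aligns each allele window to the outgroup window (pattern
#' global, subject local, so a full-length outgroup cDNA may be supplied)
#' with match +1, mismatch -1, gap open 2, gap extend 0.5. Identity is
#' matches over alignment columns. The allele with the higher identity is
#' called ancestral; a tie is unresolved. Case-insensitive.
#'
#' @param surface_seq,cave_seq Allele nucleotide windows spanning the
#'   lesion.
#' @param outgroup_seq Orthologous outgroup sequence.
#' @return List with `ancestral` (`"surface-like"`, `"cave-like"` or
#'   `"unresolved"`), `identity_surface`, `identity_cave`.
#' @export
polarize <- function(surface_seq, cave_seq, outgroup_seq) {
  if (!nzchar(surface_seq) || !nzchar(cave_seq) || !nzchar(outgroup_seq)) {
    stop("polarize requires non-empty sequences")
  }
  ids <- vapply(c(surface_seq, cave_seq), function(s) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(s)),
      Biostrings::DNAString(toupper(outgroup_seq)),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 2, gapExtension = 0.5)
    Biostrings::pid(aln, type = "PID1") / 100
  }, numeric(1))
  call <- if (ids[1L] > ids[2L]) "surface-like"
          else if (ids[2L] > ids[1L]) "cave-like" else "unresolved"
  list(ancestral = call,
       identity_surface = unname(ids[1L]),
       identity_cave = unname(ids[2L]))
}

# variant-allele window: apply observed events (reference-cDNA space) of one
# gene to the reference cDNA window [ws, we]
apply_events_to_window <- function(ref_window, ws, obs) {
  out <- ref_window
  # apply right-to-left so upstream coordinates stay valid
  o <- order(obs$ref_start, decreasing = TRUE)
  for (i in o) {
    len <- nchar(obs$sequence[i])
    if (obs$kind[i] == "deletion") {
      a <- obs$ref_start[i] - ws + 1L
      out <- paste0(substr(out, 1L, a - 1L), substr(out, a + len, nchar(out)))
    } else {
      a <- obs$ref_start[i] - ws + 1L   # anchor, insert after it
      out <- paste0(substr(out, 1L, a), obs$sequence[i],
                    substr(out, a + 1L, nchar(out)))
    }
  }
  out
}

#' Compare annotated lesions across populations
#'
#' For every annotated locus, computes per-population depth, allele
#' fraction and genotype state, the sharing class, and (when an outgroup
#' sequence is available for the gene) the ancestral polarization by
#' pairwise alignment of both allele windows to the outgroup. When
#' polarization succeeds, mutation names are re-expressed relative to the
#' ancestral allele: if the derived lineage carries extra bases the lesion
#' is an insertion, otherwise a deletion, with coordinates in the carrier
#' allele. A `shared-cave` pattern whose cave-shared allele is ancestral is
#' refined to `surface-specific`.
#'
#' @param annotated [annotate_candidates()] result.
#' @param pop_indexes Named list (one entry per population) of
#'   [index_alignments()] results.
#' @param genome [load_genome()] result.
#' @param models Named list of [gene_model()]s.
#' @param outgroup Optional [Biostrings::DNAStringSet] (or FASTA path)
#'   keyed by gene name.
#' @param config [screen_config()].
#' @return data.frame, one row per lesion locus, with per-population
#'   support columns, sharing class, ancestral call, identity scores and
#'   final names.
#' @export
compare_all <- function(annotated, pop_indexes, genome, models,
                        outgroup = NULL, config = screen_config()) {
  if (is.character(outgroup)) outgroup <- load_genome(outgroup)
  pops <- names(pop_indexes)
  stopifnot(!is.null(pops), all(nzchar(pops)))
  les <- annotated$lesions
  if (is.null(les) || nrow(les) == 0L) return(data.frame())
  rows <- list()
  for (g in unique(les$gene)) {
    lg <- les[les$gene == g, , drop = FALSE]
    model <- models[[g]]
    loci <- data.frame(scaffold = lg$scaffold, genomic_pos = lg$genomic_pos,
                       kind = lg$kind, len = nchar(lg$sequence),
                       stringsAsFactors = FALSE)
    # per-population support at each locus
    support <- lapply(pop_indexes, function(idx) {
      dp <- depth_at(idx, loci)
      alt <- vapply(seq_len(nrow(loci)), function(i) {
        ev <- idx$events
        seq_g <- if (model$strand == "-") revcomp(lg$sequence[i]) else lg$sequence[i]
        sum(ev$scaffold == loci$scaffold[i] &
              ev$genomic_pos == loci$genomic_pos[i] &
              ev$kind == loci$kind[i] & ev$sequence == seq_g)
      }, integer(1))
      list(depth = dp, alt = alt)
    })
    states <- vapply(seq_len(nrow(loci)), function(i) {
      st <- vapply(pops, function(p) {
        genotype_state(support[[p]]$depth[i], support[[p]]$alt[i], config)
      }, character(1))
      names(st) <- pops
      sharing_class(st, config$surface_pop, config$cave_pops)
    }, character(1))

    # polarization once per gene over a window spanning all its lesions
    obs <- data.frame(kind = lg$kind, ref_start = lg$ref_cdna_start,
                      sequence = lg$sequence, stringsAsFactors = FALSE)
    w <- config$polarization_window
    ws <- max(1L, min(lg$ref_cdna_start) - w)
    we <- min(model$cdna_length, max(lg$ref_cdna_end) + w)
    gspan <- sort(range(cdna_to_genomic(model, c(ws, we))))
    ref_window <- genome_slice(genome, model$scaffold, gspan[1L], gspan[2L])
    if (model$strand == "-") ref_window <- revcomp(ref_window)
    var_window <- apply_events_to_window(ref_window, ws, obs)
    variant_pops <- unique(unlist(strsplit(lg$populations, ",")))
    surface_is_variant <- config$surface_pop %in% variant_pops
    surface_window <- if (surface_is_variant) var_window else ref_window
    other_window <- if (surface_is_variant) ref_window else var_window
    if (!is.null(outgroup) && g %in% names(outgroup)) {
      pol <- polarize(surface_window, other_window,
                      as.character(outgroup[[g]]))
    } else {
      pol <- list(ancestral = "unresolved", identity_surface = NA_real_,
                  identity_cave = NA_real_)
    }

    # final polarity: derived lineage relative to the ancestral allele
    flip <- pol$ancestral == "surface-like" && surface_is_variant
    refine <- pol$ancestral == "cave-like" & states == "shared-cave"
    final_kind <- lg$kind
    if (flip) final_kind <- ifelse(lg$kind == "insertion", "deletion", "insertion")
    final_name <- vapply(seq_len(nrow(lg)), function(i) {
      name_mutation(g, lesion(final_kind[i], lg$carrier_start[i],
                              lg$carrier_end[i], lg$sequence[i]))
    }, character(1))
    final_ascii <- vapply(seq_len(nrow(lg)), function(i) {
      name_mutation(g, lesion(final_kind[i], lg$carrier_start[i],
                              lg$carrier_end[i], lg$sequence[i]), ascii = TRUE)
    }, character(1))

    df <- data.frame(
      gene = g, scaffold = lg$scaffold, genomic_pos = lg$genomic_pos,
      kind_observed = lg$kind, kind_final = final_kind,
      sequence = lg$sequence,
      name_observed = lg$name, name = final_name, name_ascii = final_ascii,
      frame_class = lg$frame_class,
      sharing_class = ifelse(refine, "surface-specific", states),
      ancestral = pol$ancestral,
      identity_surface = pol$identity_surface,
      identity_cave = pol$identity_cave,
      variant_populations = lg$populations,
      stringsAsFactors = FALSE)
    for (p in pops) {
      df[[paste0("depth_", p)]] <- support[[p]]$depth
      df[[paste0("alt_", p)]] <- support[[p]]$alt
      df[[paste0("state_", p)]] <- vapply(seq_len(nrow(loci)), function(i) {
        genotype_state(support[[p]]$depth[i], support[[p]]$alt[i], config)
      }, character(1))
    }
    rows[[g]] <- df
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
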