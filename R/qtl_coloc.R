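# Gene-to-QTL-marker distances and colocalization report. Distances are
# measured from the marker position to the nearest gene-span boundary
# (0 when the marker lies inside the span); a midpoint mode is available
# since published approximate distances do not state the measurement point.

QTL_TRAITS <- c("pigmentation", "body morphology", "sensory",
                "craniofacial morphology", "eye morphology", "jaw morphology")

#' Load a QTL marker table
#'
#' Tab-separated columns: `marker`, `trait`, `chrom`, `pos`, `source`.
#' Trait categories are restricted to the six-way vocabulary
#' (pigmentation, body morphology, sensory, craniofacial morphology,
#' eye morphology, jaw morphology).
#'
#' @param path TSV file path.
#' @return data.frame of validated markers.
#' @export
load_markers <- function(path) {
  df <- read_tsv(path)
  need <- c("marker", "trait", "chrom", "pos", "source")
  if (!all(need %in% names(df))) {
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!df$trait %in% QTL_TRAITS)
  if (length(bad)) {
    stop("unknown trait category '", df$trait[bad[1L]], "' at line ",
         bad[1L] + 1L, " (allowed: ", paste(QTL_TRAITS, collapse = "; "), ")")
  }
  df$pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(df$pos) | df$pos < 1L)
  if (length(bad)) stop("malformed marker position at line ", bad[1L] + 1L)
  df
}

#' Distance between a gene and a QTL marker
#'
#' @param model A [gene_model()].
#' @param marker One marker row (list or 1-row data.frame) with `chrom`
#'   and `pos`.
#' @param scaffold_map Optional named character vector mapping scaffold id
#'   to chromosome; scaffolds absent from the map are unplaced. `NULL`
#'   treats scaffold ids themselves as chromosomes.
#' @param mode `"boundary"` (distance to the nearest gene-span edge, 0
#'   inside the span) or `"midpoint"`.
#' @return List with `status` (`"ok"`, `"different-chromosome"` or
#'   `"unplaced"`) and `distance` (bp, or `NA`).
#' @export
gene_marker_distance <- function(model, marker, scaffold_map = NULL,
                                 mode = c("boundary", "midpoint")) {
  mode <- match.arg(mode)
  chrom <- if (is.null(scaffold_map)) model$scaffold
           else unname(scaffold_map[model$scaffold])
  if (is.null(chrom) || is.na(chrom)) {
    return(list(status = "unplaced", distance = NA_real_))
  }
  if (chrom != marker$chrom) {
    return(list(status = "different-chromosome", distance = NA_real_))
  }
  sp <- gene_span(model)
  d <- if (mode == "midpoint") {
    abs(marker$pos - mean(sp))
  } else if (marker$pos >= sp[1L] && marker$pos <= sp[2L]) {
    0
  } else {
    min(abs(marker$pos - sp))
  }
  list(status = "ok", distance = as.numeric(d))
}

#' Colocalization report for mutation-bearing genes and QTL markers
#'
#' For every gene and every marker on the same chromosome, a record with
#' the distance and a per-gene nearest-marker rank. Unplaced genes are
#' reported once with status `"unplaced"`; genes whose chromosome carries
#' no marker get one `"no-marker"` notice row.
#'
#' @param models Named list of [gene_model()]s.
#' @param markers data.frame from [load_markers()].
#' @param scaffold_map,mode See [gene_marker_distance()].
#' @return data.frame: gene, marker, trait, chrom, marker_pos, distance,
#'   status, rank.
#' @export
colocalize <- function(models, markers, scaffold_map = NULL,
                       mode = "boundary") {
  empty <- data.frame(gene = character(0), marker = character(0),
                      trait = character(0), chrom = character(0),
                      marker_pos = integer(0), distance = numeric(0),
                      status = character(0), rank = integer(0),
                      stringsAsFactors = FALSE)
  if (length(models) == 0L || nrow(markers) == 0L) return(empty)
  rows <- list()
  for (g in names(models)) {
    model <- models[[g]]
    res <- lapply(seq_len(nrow(markers)), function(i) {
      gene_marker_distance(model, markers[i, ], scaffold_map, mode)
    })
    status <- vapply(res, `[[`, "", "status")
    if (all(status == "unplaced")) {
      rows[[g]] <- data.frame(gene = g, marker = NA_character_,
                              trait = NA_character_, chrom = NA_character_,
                              marker_pos = NA_integer_, distance = NA_real_,
                              status = "unplaced", rank = NA_integer_,
                              stringsAsFactors = FALSE)
      next
    }
    ok <- which(status == "ok")
    if (length(ok) == 0L) {
      chrom <- if (is.null(scaffold_map)) model$scaffold
               else unname(scaffold_map[model$scaffold])
      rows[[g]] <- data.frame(gene = g, marker = NA_character_,
                              trait = NA_character_, chrom = chrom,
                              marker_pos = NA_integer_, distance = NA_real_,
                              status = "no-marker", rank = NA_integer_,
                              stringsAsFactors = FALSE)
      next
    }
    d <- vapply(res[ok], `[[`, 0, "distance")
    rk <- rank(d, ties.method = "first")
    rows[[g]] <- data.frame(gene = g,
                            marker = markers$marker[ok],
                            trait = markers$trait[ok],
                            chrom = markers$chrom[ok],
                            marker_pos = markers$pos[ok],
                            distance = d,
                            status = "ok",
                            rank = as.integer(rk),
                            stringsAsFactors = FALSE)[order(rk), , drop = FALSE]
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
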