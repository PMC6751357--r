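# Shared fixtures and independent oracles for the test suite. The full
# Table-1 fixture and its pipeline run are built once per session and
# cached; small per-test fixtures are built ad hoc.

.cache <- new.env(parent = emptyenv())

cached_fixture <- function() {
  if (is.null(.cache$fixture)) {
    .cache$fixture <- build_fixture(outdir = file.path(tempdir(), "fx_full"),
                                    seed = 1, depth = 60, read_length = 100,
                                    error_rate = 0)
  }
  .cache$fixture
}

cached_pipeline <- function() {
  if (is.null(.cache$pipeline)) {
    fx <- cached_fixture()
    t0 <- proc.time()[["elapsed"]]
    res <- suppressMessages(run_pipeline(
      fx$genome_fasta, fx$gff3, fx$sam,
      domains_path = fx$domains_tsv, markers_path = fx$markers_tsv,
      outgroup_path = fx$outgroup_fasta, scaffold_map = fx$scaffold_map,
      outdir = file.path(tempdir(), "run_full"), seed = 1))
    res$elapsed <- proc.time()[["elapsed"]] - t0
    .cache$pipeline <- res
  }
  .cache$pipeline
}

# a plain two-exon plus-strand model: exon1 101-200, exon2 301-400
toy_model <- function(strand = "+", cds_offset = 0L) {
  if (strand == "+") {
    gene_model("g1", "toy", "scaf", "+", c(101L, 301L), c(200L, 400L),
               cds_offset)
  } else {
    gene_model("g1", "toy", "scaf", "-", c(301L, 101L), c(400L, 200L),
               cds_offset)
  }
}

# random multi-exon model on either strand for property tests
random_model <- function(n_exons = sample(1:6, 1), strand = sample(c("+", "-"), 1)) {
  widths <- sample(5:60, n_exons, replace = TRUE)
  gaps <- sample(10:100, n_exons, replace = TRUE)
  starts <- 1L + cumsum(gaps) + c(0L, cumsum(widths[-n_exons]))
  ends <- starts + widths - 1L
  if (strand == "-") { starts <- rev(starts); ends <- rev(ends) }
  gene_model("rg", "rgene", "scaf", strand, starts, ends)
}

# one-gene spec for small fixtures; lesions given in carrier coordinates
mini_spec <- function(kind = "insertion", carrier_start = 300L,
                      carrier_end = 302L, sequence = "TGT",
                      variant_pop = "Surface", cdna_length = 600L,
                      n_exons = 3L, mutation_exon = 2L, strand = "+",
                      scaffold_bp = 1000000L) {
  genes <- data.frame(
    gene = "mini", n_exons = n_exons, mutation_exon = mutation_exon,
    cdna_length = cdna_length, strand = strand, scaffold = "scaffold_mini",
    scaffold_bp = scaffold_bp, gene_start = 10001L, depth_factor = 1,
    carrier_fraction = 1, boundary_margin = 60L, decoy = FALSE,
    stringsAsFactors = FALSE)
  lesions <- data.frame(
    gene = "mini", kind = kind, carrier_start = carrier_start,
    carrier_end = carrier_end, sequence = sequence,
    variant_pop = variant_pop, stringsAsFactors = FALSE)
  list(genes = genes, lesions = lesions)
}

mini_fixture <- function(seed = 1, depth = 60, error_rate = 0, ...) {
  build_fixture(outdir = tempfile("fx_mini"), seed = seed, depth = depth,
                error_rate = error_rate, spec = mini_spec(...))
}

# independent indel-detection oracle: align the read against the reference
# slice with Biostrings and report indel coordinates from the alignment
align_oracle <- function(read_seq, ref_seq, ref_offset) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(read_seq), Biostrings::DNAString(ref_seq),
    type = "global", gapOpening = 6, gapExtension = 1)
  ins <- Biostrings::indel(Biostrings::subject(aln))[[1L]]  # gaps in subject = insertions
  del <- Biostrings::indel(Biostrings::pattern(aln))[[1L]]  # gaps in pattern = deletions
  list(
    insertion_anchor = if (length(ins)) ref_offset + BiocGenerics::start(ins) - 2L
                       else integer(0),
    deletion_start = if (length(del)) ref_offset + BiocGenerics::start(del) - 1L
                     else integer(0),
    deletion_len = if (length(del)) BiocGenerics::width(del) else integer(0))
}

# naive codon-walk translation used as the frame-classification oracle
translate_walk <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1L, 3L * n)), no.init.codon = TRUE))
}

apply_lesion_to_seq <- function(seq, kind, pos, ins_seq = NULL, del_len = NULL) {
  if (kind == "insertion") {
    paste0(substr(seq, 1, pos), ins_seq, substr(seq, pos + 1, nchar(seq)))
  } else {
    paste0(substr(seq, 1, pos - 1), substr(seq, pos + del_len, nchar(seq)))
  }
}
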