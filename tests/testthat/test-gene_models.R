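test_that("genome loading keeps lengths and rejects bad input", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1 description", strrep("ACGT", 300000L), ">s2",
               paste(rep("A", 500), collapse = "")), fa)
  g <- load_genome(fa)
  expect_equal(names(g), c("s1", "s2"))
  expect_equal(unname(BiocGenerics::width(g)), c(1200000L, 500L))

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(load_genome(empty))

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">s1", "ACGT", ">s1", "TTTT"), dup)
  expect_error(load_genome(dup), "duplicate")
})

test_that("fixture genome round-trips through FASTA byte-identically", {
  fx <- mini_fixture(seed = 7, depth = 2, scaffold_bp = 50000L)
  g <- load_genome(fx$genome_fasta)
  expect_identical(as.character(g), as.character(fx$genome))
})

test_that("gene model invariants: exon lengths sum to cDNA length, strand order", {
  m <- toy_model()
  expect_equal(m$cdna_length, 200L)
  expect_equal(m$exons$ordinal, 1:2)
  # minus strand: ordinal 1 must be the highest genomic coordinates
  mm <- toy_model("-")
  expect_equal(mm$exons$genomic_start[1], 301L)
  expect_error(gene_model("g", "g", "s", "-", c(101L, 301L), c(200L, 400L)),
               "transcript order")
  expect_error(gene_model("g", "g", "s", "+", c(101L, 150L), c(200L, 260L)),
               "overlap")
})

test_that("genomic_to_cdna maps first bases and flags intronic positions", {
  m <- toy_model()
  expect_equal(genomic_to_cdna(m, 101L), 1L)
  expect_equal(genomic_to_cdna(m, 200L), 100L)
  expect_equal(genomic_to_cdna(m, 301L), 101L)
  expect_true(is.na(genomic_to_cdna(m, 250L)))   # intronic
  mm <- gene_model("g", "g", "s", "-", 901L, 1000L)
  expect_equal(genomic_to_cdna(mm, 1000L), 1L)
  expect_equal(cdna_to_genomic(mm, 1L), 1000L)
  expect_equal(cdna_to_genomic(m, 1L), 101L)
  expect_error(cdna_to_genomic(m, 201L), "out of range")
})

test_that("genomic<->cDNA are mutual inverses over every exonic base", {
  set.seed(42)
  for (rep in 1:10) {
    m <- random_model()
    cpos <- seq_len(m$cdna_length)
    g <- cdna_to_genomic(m, cpos)
    expect_equal(genomic_to_cdna(m, g), cpos)
    # every exonic genomic base maps back too
    gall <- unlist(Map(seq, m$exons$genomic_start, m$exons$genomic_end))
    expect_equal(sort(cdna_to_genomic(m, genomic_to_cdna(m, gall))), sort(gall))
    # intronic bases between consecutive exons are NA
    gs <- sort(m$exons$genomic_start)
    ge <- sort(m$exons$genomic_end)
    if (nrow(m$exons) > 1) {
      intron1 <- (ge[1] + 1L):(gs[2] - 1L)
      expect_true(all(is.na(genomic_to_cdna(m, intron1))))
    }
  }
})

test_that("strand reversal mirrors cDNA coordinates", {
  set.seed(11)
  for (rep in 1:5) {
    m <- random_model(n_exons = 3, strand = "+")
    flipped <- gene_model("rg", "rgene", "scaf", "-",
                          rev(m$exons$genomic_start), rev(m$exons$genomic_end))
    gall <- unlist(Map(seq, m$exons$genomic_start, m$exons$genomic_end))
    expect_equal(genomic_to_cdna(flipped, gall),
                 m$cdna_length - genomic_to_cdna(m, gall) + 1L)
  }
})

test_that("exon_of agrees with a linear scan and reports totals", {
  ghrb_like <- gene_model("g", "g", "s", "+",
                          c(1L, 301L, 601L, 901L, 1201L, 1501L, 1801L),
                          c(235L, 535L, 835L, 1135L, 1435L, 1735L, 2040L))
  expect_equal(ghrb_like$cdna_length, 1650L)
  # exon 7 spans cDNA 1411-1650 by this construction
  expect_equal(unname(exon_of(ghrb_like, 1423L)), c(7L, 7L))
  expect_equal(unname(exon_of(ghrb_like, 1L)), c(1L, 7L))
  set.seed(5)
  for (rep in 1:5) {
    m <- random_model()
    widths <- m$exons$genomic_end - m$exons$genomic_start + 1L
    for (cp in sort(sample(m$cdna_length, min(20, m$cdna_length)))) {
      scan <- which(cp <= cumsum(widths))[1]   # linear-scan oracle
      expect_equal(unname(exon_of(m, cp)[1]), scan)
    }
  }
})

test_that("exon boundary distance honors termini configuration", {
  m <- gene_model("g", "g", "s", "+", c(1L, 500L, 900L),
                  c(99L, 600L, 1100L))  # cDNA spans 1-99, 100-200, 201-402
  expect_equal(exon_boundary_distance(m, 150L), 50)
  expect_equal(exon_boundary_distance(m, 100L), 0)
  # first base of transcript: start is a terminus, not a splice boundary
  expect_equal(exon_boundary_distance(m, 1L), 98)
  expect_equal(exon_boundary_distance(m, 1L, include_termini = TRUE), 0)
  # single-exon gene has no splice boundaries at all
  single <- gene_model("g", "g", "s", "+", 1L, 500L)
  expect_equal(exon_boundary_distance(single, 250L), Inf)
  # random positions equal the min of both independently computed offsets
  set.seed(9)
  m2 <- random_model(n_exons = 4)
  widths <- m2$exons$genomic_end - m2$exons$genomic_start + 1L
  cum <- cumsum(widths)
  for (cp in sample(m2$cdna_length, 15)) {
    i <- which(cp <= cum)[1]
    lo <- if (i == 1) 1L else cum[i - 1] + 1L
    dl <- if (i == 1) Inf else cp - lo
    dr <- if (i == 4) Inf else cum[i] - cp
    expect_equal(exon_boundary_distance(m2, cp), min(dl, dr))
  }
})

test_that("GFF3 loading assigns ordinals in transcript orientation", {
  fx <- mini_fixture(seed = 3, depth = 2, strand = "-",
                     scaffold_bp = 50000L)
  models <- load_gene_models(fx$gff3, load_genome(fx$genome_fasta))
  m <- models[["mini"]]
  expect_equal(m$strand, "-")
  expect_equal(m$cdna_length, 600L)
  # minus strand: exon with highest genomic start gets ordinal 1
  expect_equal(which.max(m$exons$genomic_start), 1L)
  # identical to the in-memory model used to build the fixture
  expect_equal(m$exons, fx$models[["mini"]]$exons)
})

test_that("GFF3 loading rejects exons outside scaffold bounds", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">s1", strrep("A", 100)), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "s1\tx\tgene\t10\t500\t.\t+\t.\tID=gene:a;Name=a",
               "s1\tx\tmRNA\t10\t500\t.\t+\t.\tID=tr:a;Parent=gene:a",
               "s1\tx\texon\t10\t500\t.\t+\t.\tID=e1;Parent=tr:a"), gff)
  expect_error(load_gene_models(gff, load_genome(fa)), "scaffold bounds")
})
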