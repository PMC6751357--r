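test_that("frame classification follows divisibility by three", {
  expect_equal(classify_frame(lesion("insertion", 1423, 1425, "TGT")), "in-frame")
  expect_equal(classify_frame(lesion("deletion", 1046, 1050, "AGTTC")), "frameshift")
  expect_equal(classify_frame(lesion("insertion", 1957, 1992, strrep("A", 36))),
               "in-frame")
  expect_error(lesion("insertion", 5, 4, ""), "empty")
})

test_that("frame classification agrees with a codon-walk translation oracle", {
  set.seed(21)
  for (rep in 1:25) {
    n_codons <- sample(30:60, 1)
    cds <- paste(sample(c("GCT", "GGA", "TCC", "CTG", "AAA", "TTC"),
                        n_codons, replace = TRUE), collapse = "")
    pos <- sample(10:(nchar(cds) - 40), 1)
    len <- sample(1:9, 1)
    kind <- sample(c("insertion", "deletion"), 1)
    mutated <- if (kind == "insertion") {
      apply_lesion_to_seq(cds, "insertion", pos, ins_seq = strrep("G", len))
    } else {
      apply_lesion_to_seq(cds, "deletion", pos, del_len = len)
    }
    l <- lesion(kind, pos + 1L, pos + len, strrep("G", len))
    # compare the peptide tails well downstream of the lesion
    tail_start <- ceiling((pos + len) / 3) + 4L
    orig_tail <- substring(translate_walk(cds), tail_start)
    mut_pep <- translate_walk(mutated)
    same_tail <- endsWith(mut_pep, orig_tail) && nchar(orig_tail) > 3
    expect_equal(classify_frame(l) == "in-frame", same_tail,
                 info = paste(kind, len))
  }
})

test_that("compound frame: restoration position and net offset", {
  plg <- list(lesion("insertion", 290, 290, "T"),
              lesion("deletion", 294, 294, "C"))
  fr <- compound_frame(plg)
  expect_equal(fr$net_offset, 0L)
  expect_equal(fr$restoration_pos, 294L)
  expect_equal(fr$classes, c("frameshift", "frameshift"))

  mki67 <- list(lesion("insertion", 1957, 1992, strrep("A", 36)),
                lesion("deletion", 2154, 2156, "TTG"))
  fr2 <- compound_frame(mki67)
  expect_equal(fr2$classes, c("in-frame", "in-frame"))
  expect_equal(fr2$net_offset, 0L)
  expect_true(is.na(fr2$restoration_pos))       # never left frame
  expect_true(all(fr2$track$offset == 0L))

  expect_equal(compound_frame(list())$net_offset, 0L)
  expect_error(compound_frame(list(lesion("deletion", 10, 14, "AAAAA"),
                                   lesion("insertion", 12, 12, "G"))),
               "overlap")
})

test_that("net offset is invariant under splitting a lesion into 1-bp pieces", {
  set.seed(8)
  for (rep in 1:10) {
    len <- sample(2:8, 1)
    start <- sample(50:200, 1)
    whole <- compound_frame(list(lesion("deletion", start, start + len - 1L,
                                        strrep("A", len))))
    pieces <- lapply(seq_len(len), function(i)
      lesion("deletion", start + i - 1L, start + i - 1L, "A"))
    expect_equal(compound_frame(pieces)$net_offset, whole$net_offset)
  }
})

test_that("cDNA-to-protein mapping matches the published residue positions", {
  expect_equal(cdna_to_protein(290), 97L)
  expect_equal(cdna_to_protein(294), 98L)
  expect_equal(cdna_to_protein(1046), 349L)
  expect_equal(cdna_to_protein(1050), 350L)
  expect_equal(cdna_to_protein(1423), 475L)
  expect_equal(cdna_to_protein(3), 1L)
  expect_equal(cdna_to_protein(4), 2L)
  expect_equal(cdna_to_protein(10, cds_offset = 3), 3L)
  expect_error(cdna_to_protein(2, cds_offset = 3), "5'")
})

test_that("residue gain for in-frame lesions", {
  expect_equal(residue_gain(lesion("insertion", 1957, 1992, strrep("A", 36))), 12L)
  expect_equal(residue_gain(lesion("insertion", 247, 258, "ATGGACAACATC")), 4L)
  expect_equal(residue_gain(lesion("insertion", 1423, 1425, "TGT")), 1L)
  expect_error(residue_gain(lesion("deletion", 1, 5, "AAAAA")), "in-frame")
})

test_that("mutation names match the published style and round-trip", {
  expect_equal(name_mutation("ghrb", lesion("insertion", 1423, 1425, "TGT")),
               "ghrb^Ins1423–1425")
  expect_equal(name_mutation("plg", lesion("insertion", 290, 290, "T")),
               "plg^Ins290")
  expect_equal(name_mutation("rnf126", lesion("deletion", 1046, 1050, "AGTTC")),
               "rnf126^Δ1046–1050")
  expect_equal(name_mutation("rnf126", lesion("deletion", 1046, 1050, "AGTTC"),
                             ascii = TRUE),
               "rnf126^del1046-1050")
  # parser inverts both dialects
  set.seed(3)
  seen <- character(0)
  for (rep in 1:20) {
    kind <- sample(c("insertion", "deletion"), 1)
    a <- sample(1:3000, 1); len <- sample(1:40, 1)
    l <- lesion(kind, a, a + len - 1L, strrep("C", len))
    for (ascii in c(FALSE, TRUE)) {
      nm <- name_mutation("gene1", l, ascii = ascii)
      p <- parse_mutation_name(nm)
      expect_equal(p$kind, kind)
      expect_equal(p$cdna_start, a)
      expect_equal(p$cdna_end, a + len - 1L)
    }
    seen <- c(seen, name_mutation("gene1", l))
  }
  # injective over distinct (kind, interval) triples
  expect_equal(anyDuplicated(seen), 0L)
})

test_that("domain overlap uses closed intervals, touching counts", {
  domains <- load_domains(system.file("extdata", "protein_domains.tsv",
                                      package = "cavescreen"))
  expect_equal(domain_overlap(475, 475, domains, gene = "ghrb")$domain_name,
               "GHBP")
  expect_equal(nrow(domain_overlap(349, 350, domains, gene = "mia3")), 0L)
  mki <- domain_overlap(656, 667, domains, gene = "mki67")
  expect_setequal(mki$domain_name,
                  c("Herpes_BLLF1", "PTZ00449", "PHA03247", "retinal"))
  # touching at a single residue counts as impacted
  one <- data.frame(gene = "x", domain_name = "D", aa_start = 10L, aa_end = 20L)
  expect_equal(nrow(domain_overlap(20, 25, one)), 1L)
  expect_equal(nrow(domain_overlap(21, 25, one)), 0L)
})

test_that("premature stop scanning finds the first in-frame stop", {
  expect_equal(premature_stop("ATGAAATAAGGG"), 3L)
  expect_true(is.na(premature_stop("ATGAAAGGG")))
  expect_equal(premature_stop("CCATGTAAGGG", cds_offset = 2L), 2L)
})
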