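# Caller tests run against hand-built SAM records and against the
# generator's truth tables; the independent oracle re-detects each event by
# string alignment of the read against the reference slice.

make_genome <- function(seq, name = "s1") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", name), seq), fa)
  load_genome(fa)
}

read_row <- function(pos, cigar, seq, qname = "r1", flag = 0L, rname = "s1") {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             cigar = cigar, seq = seq, stringsAsFactors = FALSE)
}

test_that("CIGAR walk positions insertions and deletions correctly", {
  set.seed(12)
  ref <- random_dna(200)
  # shift-proof flanks so the planted coordinates are already left-aligned
  # and the alignment oracle has a unique gap placement
  substr(ref, 109, 110) <- "CA"   # TGT insertion after 109
  substr(ref, 54, 54) <- "A"      # deletion of 55-59
  substr(ref, 55, 59) <- "GCTGC"
  substr(ref, 60, 60) <- "T"
  genome <- make_genome(ref)

  # insertion: read at pos 100, 10M3I10M -> anchored at 109
  rs <- paste0(substr(ref, 100, 109), "TGT", substr(ref, 110, 119))
  ev <- extract_events(read_row(100L, "10M3I10M", rs), genome)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$genomic_pos, 109L)
  expect_equal(ev$sequence, "TGT")
  # oracle: realign the read to the reference slice
  orc <- align_oracle(rs, substr(ref, 100, 119), 100L)
  expect_equal(orc$insertion_anchor, 109L)

  # pure match produces nothing
  expect_equal(nrow(extract_events(read_row(100L, "20M",
                                            substr(ref, 100, 119)), genome)), 0L)

  # deletion: read at pos 50, 5M5D5M -> first deleted base 55, length 5
  rs2 <- paste0(substr(ref, 50, 54), substr(ref, 60, 64))
  ev2 <- extract_events(read_row(50L, "5M5D5M", rs2), genome)
  expect_equal(ev2$kind, "deletion")
  expect_equal(ev2$genomic_pos, 55L)
  expect_equal(ev2$sequence, toupper(substr(ref, 55, 59)))
  orc2 <- align_oracle(rs2, substr(ref, 50, 64), 50L)
  expect_equal(orc2$deletion_start, 55L)
  expect_equal(orc2$deletion_len, 5L)

  # unmapped read yields nothing
  expect_equal(nrow(extract_events(read_row(100L, "20M",
                                            substr(ref, 100, 119), flag = 4L),
                                   genome)), 0L)
})

test_that("events are left-aligned in repeat context before merging", {
  # reference with an AAAA homopolymer starting at 11
  ref <- paste0(random_dna(10), "AAAA", random_dna(60))
  substr(ref, 10, 10) <- "C"; substr(ref, 15, 15) <- "G"
  genome <- make_genome(ref)
  # an A inserted after the last A is equivalent to one after the first:
  # both reads must merge to the same site
  mk <- function(anchor) {
    s <- paste0(substr(ref, 5, anchor), "A", substr(ref, anchor + 1, anchor + 8))
    read_row(5L, sprintf("%dM1I8M", anchor - 5L + 1L), s, qname = paste0("r", anchor))
  }
  reads <- rbind(mk(14L), mk(11L))
  ev <- cavescreen:::extract_events_batch(reads, genome)
  expect_equal(unique(ev$genomic_pos), 10L)   # shifted to the repeat's left edge
  expect_equal(unique(ev$sequence), "A")
  sites <- pileup_sites(reads, genome, "pop")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$alt_count, 2L)
})

test_that("pileup merges identical events and separates distinct alleles", {
  set.seed(4)
  ref <- random_dna(300)
  genome <- make_genome(ref)
  mkread <- function(i, ins) {
    s <- paste0(substr(ref, 100, 149), ins, substr(ref, 150, 199))
    read_row(100L, "50M3I50M", s, qname = paste0("r", i))
  }
  # 99 reads TGT, 1 read with a different allele, plus 10 spanning refs
  reads <- do.call(rbind, c(lapply(1:99, mkread, ins = "TGT"),
                            list(mkread(100, "GCA")),
                            lapply(101:110, function(i)
                              read_row(100L, "100M", substr(ref, 100, 199),
                                       qname = paste0("r", i)))))
  sites <- pileup_sites(reads, genome, "Surface")
  expect_equal(nrow(sites), 2L)
  tgt <- sites[sites$sequence == "TGT", ]
  expect_equal(tgt$depth, 110L)
  expect_equal(tgt$alt_count, 99L)
  expect_equal(tgt$allele_fraction, 99 / 110)
  expect_true(sum(sites$alt_count) <= unique(sites$depth)[1])
})

test_that("caller output is invariant to read input order", {
  fx <- mini_fixture(seed = 5, depth = 10, scaffold_bp = 50000L)
  reads <- read_alignments(fx$sam[["Surface"]])
  s1 <- pileup_sites(reads, fx$genome, "Surface")
  set.seed(99)
  s2 <- pileup_sites(reads[sample(nrow(reads)), ], fx$genome, "Surface")
  rownames(s2) <- NULL
  expect_equal(s1, s2)
})

test_that("caller recovers exactly the generator's truth on error-free reads", {
  # zero false negatives, zero spurious sites, allele fraction 1.0
  for (seed in 1:5) {
    fx <- mini_fixture(seed = seed, depth = 20, scaffold_bp = 50000L,
                       kind = sample(c("insertion", "deletion"), 1),
                       sequence = "ACGTT", carrier_start = 300L,
                       carrier_end = 304L)
    reads <- read_alignments(fx$sam[["Surface"]])
    sites <- pileup_sites(reads, fx$genome, "Surface")
    expect_equal(nrow(sites), 1L, info = paste("seed", seed))
    expect_equal(sites$genomic_pos, fx$truth$genomic_pos)
    expect_equal(sites$sequence, fx$truth$sequence_genomic)
    expect_equal(sites$allele_fraction, 1.0)
    # alt_count equals the generator's carrier bookkeeping
    expect_equal(sites$alt_count,
                 length(unique(fx$read_truth$read_id[
                   fx$read_truth$population == "Surface"])))
  }
})

test_that("injected allele fraction is recovered within sampling error", {
  fx <- mini_fixture(seed = 2, depth = 60, scaffold_bp = 50000L)
  fx$spec$genes$carrier_fraction <- 0.98
  fx2 <- build_fixture(outdir = tempfile("fx98"), seed = 2, depth = 60,
                       spec = fx$spec)
  sites <- pileup_sites(read_alignments(fx2$sam[["Surface"]]), fx2$genome,
                        "Surface")
  expect_equal(nrow(sites), 1L)
  expect_lt(abs(sites$allele_fraction - 0.98), 2 / 60)
})

test_that("BAM input gives identical calls to SAM input", {
  fx <- mini_fixture(seed = 6, depth = 5, scaffold_bp = 50000L)
  bam <- Rsamtools::asBam(fx$sam[["Surface"]], destination = tempfile(),
                          indexDestination = FALSE)
  s_sam <- pileup_sites(read_alignments(fx$sam[["Surface"]]), fx$genome, "p")
  s_bam <- pileup_sites(read_alignments(bam), fx$genome, "p")
  expect_equal(s_sam, s_bam)
})
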