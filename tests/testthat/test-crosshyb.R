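test_that("genome variants are built with the four conversion states", {
  v <- build_genome_variants(c(chrA = "AACG"))
  expect_equal(as.character(v$dna$fwd[[1]]), "AACG")
  expect_equal(as.character(v$dna$fwd_bis[[1]]), "AATG")
  expect_equal(as.character(v$dna$rev[[1]]), "CGTT")
  expect_equal(as.character(v$dna$rev_bis[[1]]), "TGTT")
  # reverse is an involution
  rr <- build_genome_variants(setNames(as.character(v$dna$rev[[1]]), "chrA"))
  expect_equal(as.character(rr$dna$rev[[1]]), "AACG")
  # a genome without C or G is identical up to orientation
  v2 <- build_genome_variants(c(chrA = "ATTA"))
  expect_equal(as.character(v2$dna$fwd[[1]]),
               as.character(v2$dna$fwd_bis[[1]]))
  expect_equal(as.character(v2$dna$rev[[1]]),
               as.character(v2$dna$rev_bis[[1]]))
  expect_error(build_genome_variants(c(chrA = "")), "empty")
})

test_that("47 ungapped matches score exactly 44 and pass; 46 fail", {
  g <- fixture_genome(6000, 0.03, seed = 7)
  cp <- fixture_cpgs(g)
  r <- design_probe(g, "chr1", cp$mapinfo[3], "T", "C", "I")
  pl3 <- plant_offtarget(g, r, n_mismatches = 3, location = 4500, seed = 2)
  v <- build_genome_variants(pl3$genome)
  alns <- align_probe(r$allele_a_seq, v, min_matches = 40,
                      probe_id = r$ilmn_id)
  off3 <- alns[alns$plus_start > 4400 & alns$plus_start < 4600, ]
  expect_equal(off3$matches, 47L)
  expect_equal(off3$mismatches, 3L)
  expect_equal(off3$score, 44L)
  pass <- filter_alignments(alns)
  expect_true(any(pass$plus_start == off3$plus_start))

  # four substitutions: 46 matches, fails the filter
  pl4 <- plant_offtarget(g, r, n_mismatches = 4, location = 4500, seed = 3)
  v4 <- build_genome_variants(pl4$genome)
  alns4 <- align_probe(r$allele_a_seq, v4, min_matches = 40,
                       probe_id = r$ilmn_id)
  off4 <- alns4[alns4$plus_start > 4400 & alns4$plus_start < 4600, ]
  expect_equal(off4$matches, 46L)
  pass4 <- filter_alignments(alns4)
  expect_false(any(pass4$plus_start == off4$plus_start))

  # score formula consistency for ungapped 50-mers: score = 2*matches - 50
  ungapped <- alns[alns$qgap_open == 0 & alns$tgap_open == 0, ]
  expect_equal(ungapped$score, 2L * ungapped$matches - 50L)

  # gapped worked example: 48 matches, 2 mismatches, 1 query gap -> 45
  expect_equal(48L - 2L - 1L - 0L, 45L)
})

test_that("probe length and alphabet are validated", {
  v <- build_genome_variants(c(chrA = strrep("ACGT", 100)))
  expect_error(align_probe("ACGT", v), "length")
  expect_error(align_probe(strrep("Z", 50), v), "alphabet")
})

test_that("degenerate probe bases match either alternative, never mismatch", {
  seg <- paste0(strrep("A", 20), "TGGATGCCTA", "CGTTAGGCAT",
                strrep("T", 10), strrep("C", 10))
  g <- c(chrA = paste0(strrep("G", 25), seg, strrep("G", 25)))
  v <- build_genome_variants(g)
  probe <- substr(seg, 1, 50)
  # plant R over an A and a G position, Y over a C and a T position
  p <- strsplit(probe, "")[[1]]
  p[3] <- "R"; p[22] <- "R"   # over A and G
  p[28] <- "Y"; p[31] <- "Y"  # over T and T
  hit <- align_probe(paste(p, collapse = ""), v, min_matches = 50)
  expect_true(any(hit$variant == "fwd" & hit$matches == 50))
})

test_that("aligner hit set equals the exhaustive edit-distance oracle", {
  g <- fixture_genome(10000, 0.025, seed = 13)
  cp <- fixture_cpgs(g)
  r1 <- design_probe(g, "chr1", cp$mapinfo[2], "T", "C", "I")
  r2 <- design_probe(g, "chr1", cp$mapinfo[6], "B", "C", "I")
  g <- plant_offtarget(g, r1, n_mismatches = 3, location = 7000,
                       seed = 2)$genome
  g <- plant_offtarget(g, r2, n_mismatches = 1, n_del = 2,
                       location = 8000, seed = 3)$genome
  v <- build_genome_variants(g)
  for (r in list(r1, r2)) {
    alns <- align_probe(r$allele_a_seq, v, probe_id = r$ilmn_id)
    oracle <- oracle_edit_scan(r$allele_a_seq, v)
    aln_space <- alignment_space(alns$variant, alns$strand)
    ora_space <- paste(oracle$store, oracle$ori, sep = "|")
    # one aligner hit per oracle cluster per search space, overlapping it
    expect_equal(nrow(alns), nrow(oracle))
    for (i in seq_len(nrow(oracle))) {
      in_space <- which(aln_space == ora_space[i] &
                          alns$chrom == oracle$chrom[i])
      ok <- alns$plus_start[in_space] <= oracle$plus_hi[i] &
        alns$plus_end[in_space] >= oracle$plus_lo[i]
      expect_equal(sum(ok), 1L)
    }
  }
})

test_that("target transposition walks blocks and extrapolates terminal diagonals", {
  # spec-style worked example: ungapped on-target q0-49 <-> t1001-1050
  on <- tibble::tibble(
    probe_id = "p", variant = "fwd", chrom = "chr1", strand = "+",
    matches = 50L, mismatches = 0L, qgap_open = 0L, tgap_open = 0L,
    score = 50L, plus_start = 1001L, plus_end = 1050L,
    blocks = list(data.frame(qstart = 0L, pstart = 1000L, len = 50L)))
  # gapped off-target: blocks (q0-19 <-> t7001-7020), (q21-49 <-> t7021-7049)
  off <- tibble::tibble(
    probe_id = "p", variant = "fwd", chrom = "chr1", strand = "+",
    matches = 49L, mismatches = 0L, qgap_open = 0L, tgap_open = 1L,
    score = 48L, plus_start = 7001L, plus_end = 7049L,
    blocks = list(data.frame(qstart = c(0L, 21L),
                             pstart = c(7000L, 7020L),
                             len = c(20L, 29L))))
  # target 1010 -> query offset 9 -> off-target 7010
  tr <- transpose_target_to_offtargets(on, 1010L, off)
  expect_equal(tr$coord, 7010L)
  # offset 25 lands in the second block -> 7025
  on25 <- on; on25$blocks <- list(data.frame(qstart = 0L, pstart = 1000L,
                                             len = 50L))
  tr25 <- transpose_target_to_offtargets(on25, 1026L, off)
  expect_equal(tr25$coord, 7025L)
  # offset 20 falls in the unaligned gap -> skipped and counted
  tr20 <- transpose_target_to_offtargets(on, 1021L, off)
  expect_equal(nrow(tr20), 0L)
  expect_equal(attr(tr20, "n_skipped"), 1L)
  # transposing the on-target onto itself is the identity
  self <- transpose_target_to_offtargets(on, 1010L, on)
  expect_equal(self$coord, 1010L)
  # a coordinate with no diagonal through the alignment errors
  far <- on
  far$blocks <- list(data.frame(qstart = c(0L, 30L),
                                pstart = c(1000L, 1040L),
                                len = c(20L, 20L)))
  expect_error(transpose_target_to_offtargets(far, 1025L, off),
               "outside")
})

test_that("planted off-targets are recovered at exactly the planted coordinates", {
  g <- fixture_genome(9000, 0.03, seed = 31)
  cp <- fixture_cpgs(g)
  combos <- list(c("T", "C", "I"), c("B", "C", "II"), c("T", "O", "II"))
  locs <- c(6200, 6900, 7600)
  truths <- list(); mf <- NULL
  for (i in seq_along(combos)) {
    r <- design_probe(g, "chr1", cp$mapinfo[2 * i], combos[[i]][1],
                      combos[[i]][2], combos[[i]][3])
    pl <- plant_offtarget(g, r, n_mismatches = (i - 1) %% 2,
                          n_del = if (i == 3) 1 else 0,
                          location = locs[i], seed = i)
    g <- pl$genome
    truths[[i]] <- pl$truth
    mf <- dplyr::bind_rows(mf, r)
  }
  v <- build_genome_variants(g)
  hits <- map_offtargets(mf, v)
  for (t in truths) {
    got <- hits[hits$ilmn_id == t$probe_id, ]
    expect_equal(nrow(got), 1L)
    expect_equal(got$coord, t$expected_coord)
    # the planted copy still carries the interrogated cytosine in CpG context
    expect_equal(got$dinucleotide_class, "CpG")
  }
  flags <- attr(hits, "probe_flags")
  expect_true(all(flags$category == "cross_hybridising"))
})

test_that("off-target bases classify as CpG, CpH or nonC with orientation", {
  g <- c(chrA = "TTACGTTCAAG")
  # plus strand: C at 4 followed by G -> CpG; C at 8 followed by A -> CpH
  expect_equal(classify_offtarget_base("chrA", 4L, g, "+")$dinucleotide_class,
               "CpG")
  cls <- classify_offtarget_base("chrA", 8L, g, "+")
  expect_equal(cls$base, "C")
  expect_equal(cls$dinucleotide_class, "CpH")
  # T -> nonC
  expect_equal(classify_offtarget_base("chrA", 6L, g, "+")$base, "T")
  expect_equal(classify_offtarget_base("chrA", 6L, g, "+")$dinucleotide_class,
               "nonC")
  # minus orientation: the G at 5 reads as C, preceded on plus by C at 4,
  # i.e. followed in minus orientation by G -> CpG
  mcls <- classify_offtarget_base("chrA", 5L, g, "-")
  expect_equal(mcls$base, "C")
  expect_equal(mcls$dinucleotide_class, "CpG")
  # contig end: C with unknown successor flagged undecidable
  g2 <- c(chrA = "TTAC")
  endcls <- classify_offtarget_base("chrA", 4L, g2, "+")
  expect_true(endcls$undecidable)
  expect_error(classify_offtarget_base("chrA", 99L, g2, "+"), "bounds")
})

test_that("every probe lands in exactly one scan category", {
  g <- fixture_genome(8000, 0.03, seed = 17)
  cp <- fixture_cpgs(g)
  r_clean <- design_probe(g, "chr1", cp$mapinfo[2], "T", "C", "I")
  r_ch <- design_probe(g, "chr1", cp$mapinfo[5], "T", "C", "I")
  pl <- plant_offtarget(g, r_ch, n_mismatches = 2, location = 7000,
                        seed = 5)
  g <- pl$genome
  # a probe with no homology anywhere: random sequence absent from genome
  set.seed(1)
  r_none <- r_clean
  r_none$ilmn_id <- "cg_none_TC11"; r_none$name <- "cg_none"
  r_none$allele_a_seq <- paste(sample(c("A", "C", "G", "T"), 50,
                                      replace = TRUE), collapse = "")
  # a probe whose manifest coordinate is wrong (no homology at MAPINFO)
  r_wrong <- design_probe(g, "chr1", cp$mapinfo[8], "T", "C", "I")
  r_wrong$mapinfo <- 3L
  mf <- dplyr::bind_rows(r_clean, r_ch, r_none, r_wrong)
  hits <- map_offtargets(mf, build_genome_variants(g))
  flags <- attr(hits, "probe_flags")
  expect_equal(flags$category[flags$ilmn_id == r_clean$ilmn_id],
               "not_cross_hybridising")
  expect_equal(flags$category[flags$ilmn_id == r_ch$ilmn_id],
               "cross_hybridising")
  expect_equal(flags$category[flags$ilmn_id == "cg_none_TC11"],
               "no_homology")
  expect_equal(flags$category[flags$ilmn_id == r_wrong$ilmn_id],
               "no_mapinfo_homology")
  expect_equal(nrow(flags), 4L)
})

test_that("PSL records parse field-by-field with and without header", {
  psl_line <- paste(
    c(47, 3, 0, 0, 0, 0, 0, 0, "+", "probe1", 50, 0, 50, "chr1", 10000,
      999, 1049, 1, "50,", "0,", "999,"), collapse = "\t")
  path <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_line, path)
  a <- read_psl(path)
  expect_equal(a$matches, 47L)
  expect_equal(a$mismatches, 3L)
  expect_equal(a$score, 44L)
  expect_equal(a$plus_start, 1000L)
  expect_equal(a$plus_end, 1049L)
  expect_equal(a$blocks[[1]],
               data.frame(qstart = 0L, pstart = 999L, len = 50L))

  # 5-line header is skipped
  writeLines(c("psLayout version 3", "", "match\tmis-\trep.",
               "     \tmatch\tmatch",
               "---------------------------------", psl_line), path)
  expect_equal(nrow(read_psl(path)), 1L)

  writeLines("only\tthree\tcolumns", path)
  expect_error(read_psl(path), "line 1")
})

test_that("minus-strand PSL round-trips coordinates through the blocks", {
  # probe = reverse complement of genome segment [1001, 1050]
  g <- fixture_genome(3000, 0.02, seed = 8)
  seg <- substr(g[["chr1"]], 1001, 1050)
  probe <- revcomp(seg)
  psl_line <- paste(
    c(50, 0, 0, 0, 0, 0, 0, 0, "-", "probeM", 50, 0, 50, "chr1",
      nchar(g[["chr1"]]), 1000, 1050, 1, "50,", "0,", "1000,"),
    collapse = "\t")
  path <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl_line, path)
  a <- read_psl(path)
  expect_equal(a$strand, "-")
  # sequence-extraction oracle: walking every query offset through the
  # blocks must read out the complement of the probe base
  for (q in c(0L, 9L, 49L)) {
    coord <- epickit:::coord_of_query_offset(a$blocks[[1]], a$strand, q)
    genome_base <- substr(g[["chr1"]], coord, coord)
    probe_base <- substr(probe, q + 1L, q + 1L)
    expect_equal(chartr("ACGT", "TGCA", probe_base), genome_base)
  }
  # and the inverse map recovers the offset
  q9 <- epickit:::query_offset_of_coord(a$blocks[[1]], a$strand, 1041L)
  expect_equal(epickit:::coord_of_query_offset(a$blocks[[1]], a$strand, q9),
               1041L)
})
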