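# Sequence-feature annotation: ORF/UTRs, poly(A) signals, protein stats,
# IRE stem-loops, exon-intron mapping.

test_that("find_orf locates ATG..stop frames and derives UTRs", {
  o <- find_orf("ATGAAATAA")
  expect_equal(o$start, 1L)
  expect_equal(o$end, 9L)
  expect_equal(o$protein, "MK")
  expect_equal(c(o$utr5_length, o$utr3_length), c(0L, 0L))

  expect_error(find_orf(strrep("A", 60)), "no ORF")
  expect_error(find_orf("ATGAAACCC"), "no ORF")    # start but no stop

  # longest wins; 5'-most on ties
  s <- paste0("CCATGTAACC", "ATGAAAAAATAA")  # 6-nt ORF then 12-nt ORF
  o <- find_orf(s)
  expect_equal(o$start, 11L)
  expect_equal(o$length_nt, 12L)
})

test_that("ORF partition identity holds on designed cDNAs", {
  set.seed(17)
  for (i in 1:10) {
    u5 <- sample(0:200, 1); u3 <- sample(0:200, 1)
    len <- 3L * sample(4:120, 1)
    s <- simulate_cdna(u5, len, u3)
    o <- find_orf(s)
    expect_equal(o$utr5_length, u5)
    expect_equal(o$length_nt, len)
    expect_equal(o$utr3_length, u3)
    expect_equal(o$utr5_length + o$length_nt + o$utr3_length,
                 nchar(s$residues))
    expect_equal(nchar(o$protein), len / 3 - 1)
  }
})

test_that("scan_polya_signal reports all (overlapping) occurrences", {
  hits <- scan_polya_signal("GGATTAAAGG")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 8L)

  expect_equal(nrow(scan_polya_signal(strrep("GC", 30))), 0L)

  hits <- scan_polya_signal("AATAAATTAAA")
  expect_equal(hits$motif, c("AATAAA", "ATTAAA"))
  expect_equal(hits$start, c(1L, 6L))
  expect_equal(hits$end, c(6L, 11L))
})

test_that("protein_stats computes mass additively and flags unknowns", {
  g <- protein_stats("G")
  expect_equal(g$molecular_mass, 75.07, tolerance = 1e-3)

  mk <- protein_stats("MK")
  m <- protein_stats("M"); k <- protein_stats("K")
  water <- 18.01524
  expect_equal(mk$molecular_mass,
               m$molecular_mass + k$molecular_mass - water,
               tolerance = 1e-9)

  set.seed(23)
  aa <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 n, replace = TRUE), collapse = "")
  for (i in 1:5) {
    s1 <- aa(30); s2 <- aa(45)
    expect_equal(protein_stats(paste0(s1, s2))$molecular_mass,
                 protein_stats(s1)$molecular_mass +
                   protein_stats(s2)$molecular_mass - water,
                 tolerance = 1e-9)
  }

  expect_error(protein_stats("MKX"), "unknown residue 'X' at position 3")
  # basic sanity on the charge model
  expect_gt(protein_stats("KKKK")$isoelectric_point,
            protein_stats("DDDD")$isoelectric_point)
})

test_that("detect_ire matches the published 27-nt element", {
  m <- detect_ire(IRE_27MER)
  expect_equal(nrow(m), 1L)
  expect_equal(m$loop_start, 12L)
  expect_equal(m$loop_end, 17L)
  expect_equal(m$loop_seq, "CAGUGA")
  expect_equal(m$bulge_pos, 6L)
  expect_equal(m$upper_stem_pairs, 5L)
  expect_equal(m$lower_stem_pairs, 4L)   # terminal C.C cannot pair
})

test_that("detect_ire policy knobs behave", {
  mutated <- sub("cagtga", "cagcga", IRE_27MER)
  expect_equal(nrow(detect_ire(mutated)), 0L)

  # T/U and case invariance
  rna <- chartr("t", "u", IRE_27MER)
  expect_equal(detect_ire(rna), detect_ire(toupper(IRE_27MER)))
  expect_equal(detect_ire(rna), detect_ire(IRE_27MER))

  # the element needs wobble pairs in both stems
  expect_equal(nrow(detect_ire(IRE_27MER, allow_wobble = FALSE)), 0L)
  # raising the lower-stem requirement past what the element has drops it
  expect_equal(nrow(detect_ire(IRE_27MER, lower_stem_min = 5)), 0L)
  # loop motif alone is not enough: need the stems
  expect_equal(nrow(detect_ire("AAACAGUGAAAA")), 0L)
})

test_that("map_exons handles constructed and trivial instances", {
  e1 <- "ATGGCCATTCTAATGGGCCG"; e2 <- "CTCGAGCATGCATCTAGAGG"
  filler <- strrep("TC", 13)
  genomic <- paste0(e1, "GT", filler, "AG", e2)
  model <- map_exons(paste0(e1, e2), genomic)
  expect_equal(nrow(model$exons), 2L)
  expect_equal(model$exons$start, c(1L, 51L))
  expect_equal(model$exons$end, c(20L, 70L))
  expect_equal(model$introns$donor, "GT")
  expect_equal(model$introns$acceptor, "AG")
  expect_true(all(model$introns$canonical))

  same <- strrep("ACGTTGCA", 10)
  m1 <- map_exons(same, same)
  expect_equal(nrow(m1$exons), 1L)
  expect_equal(nrow(m1$introns), 0L)

  expect_error(map_exons(paste0(e1, e2), paste0(e1, "GT", filler, "AG")),
               "position")
  expect_error(map_exons(paste0(e1, e2), e1), "longer")
})

test_that("round-trip: re-mapping a simulated gene model is exact", {
  set.seed(41)
  for (i in 1:20) {
    sim <- simulate_gene_model(n_exons = sample(2:5, 1),
                               flank = sample(c(0L, 25L), 1))
    expect_equal(splice_gene_model(sim$genomic, sim$model), sim$cdna)
    model <- map_exons(sim$cdna, sim$genomic)
    expect_equal(model$exons, sim$model$exons)
    expect_equal(model$introns$start, sim$model$introns$start)
    expect_equal(model$introns$end, sim$model$introns$end)
    expect_true(all(model$introns$canonical))
    # exon + intron lengths tile the spanned genomic region
    span <- model$total_genomic_length
    expect_equal(sum(model$exons$end - model$exons$start + 1L) +
                   sum(model$introns$end - model$introns$start + 1L), span)
  }
})

test_that("annotate_transcript assembles the full report", {
  s <- simulate_cdna(seed = 9)
  ann <- annotate_transcript(s)
  expect_s3_class(ann, "transcript_annotation")
  expect_equal(ann$orf$length_nt, 525L)
  expect_equal(ann$protein$length_aa, 174L)
  tbl <- annotation_table(ann)
  expect_true(all(c("five_prime_UTR", "CDS", "three_prime_UTR") %in%
                    tbl$feature))
  expect_true(all(tbl$start >= 1L & tbl$end >= tbl$start))

  # insert one canonical intron and confirm the genomic mapping appears
  cd <- s$residues
  cut <- 400L
  while (substr(cd, cut + 1L, cut + 1L) == "G") cut <- cut + 1L
  genomic <- paste0(substr(cd, 1L, cut), "GT", strrep("CT", 20), "AG",
                    substr(cd, cut + 1L, nchar(cd)))
  ann2 <- annotate_transcript(s, genomic = genomic)
  expect_equal(nrow(ann2$gene_model$exons), 2L)
  expect_true("intron" %in% annotation_table(ann2)$feature)
})
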