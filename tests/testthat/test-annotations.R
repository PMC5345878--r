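test_that("BED12 parsing follows the 0-based half-open block convention", {
  f <- tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t400\tgeneA\t0\t+\t100\t400\t0\t2\t100,100\t0,200",
    "chr1\t100\t400\tgeneB\t0\t-\t100\t400\t0\t2\t100,100\t0,200"), f)
  m <- load_gene_models(f, "bed12")
  expect_equal(m$gene_id, c("geneA", "geneB"))
  expect_equal(unname(m$exons[[1]][, "start"]), c(100L, 300L))
  expect_equal(unname(m$exons[[1]][, "end"]), c(200L, 400L))
  expect_equal(m$tss, c(100L, 399L))
})

test_that("GTF 1-based inclusive coordinates convert to half-open", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    f)
  m <- load_gene_models(f, "gtf")
  expect_equal(unname(m$exons[[1]][1, ]), c(100L, 200L))
  expect_equal(unname(m$exons[[1]][2, ]), c(300L, 400L))
})

test_that("canonical transcript is the longest, ties by transcript id", {
  f <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ts\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "tB";',
    'chr1\ts\texon\t101\t300\t.\t+\t.\tgene_id "g1"; transcript_id "tA";',
    'chr1\ts\texon\t501\t700\t.\t+\t.\tgene_id "g2"; transcript_id "tZ";',
    'chr1\ts\texon\t501\t700\t.\t+\t.\tgene_id "g2"; transcript_id "tY";'),
    f)
  m <- load_gene_models(f, "gtf")
  # g1: tA is longer; g2: equal lengths, tY wins lexicographically
  expect_equal(unname(m$exons[[which(m$gene_id == "g1")]][, "end"]), 300L)
  expect_equal(nrow(m), 2L)
})

test_that("empty and malformed annotation files are rejected", {
  f <- tempfile(fileext = ".bed")
  writeLines(character(), f)
  expect_error(load_gene_models(f, "bed12"))
  f2 <- tempfile(fileext = ".gtf")
  writeLines("not\ta\tgtf", f2)
  expect_error(load_gene_models(f2, "gtf"))
})

test_that("BED12 round-trip preserves coordinates and strands", {
  m <- toy_multi_models(4L)
  f <- tempfile(fileext = ".bed")
  write_bed12(m, f)
  m2 <- load_gene_models(f, "bed12")
  expect_equal(m2$gene_id, m$gene_id)
  expect_equal(m2$strand, m$strand)
  expect_equal(m2$tss, m$tss)
  for (i in seq_len(nrow(m)))
    expect_equal(m2$exons[[i]], m$exons[[i]])
})

test_that("boundary anchors sit on the correct side of each splice site", {
  mp <- toy_two_exon_models("+")
  expect_equal(extract_anchors(mp, "intron_exon")$pos, 300L)
  expect_equal(extract_anchors(mp, "exon_intron")$pos, 200L)
  mm <- toy_two_exon_models("-")
  expect_equal(extract_anchors(mm, "intron_exon")$pos, 199L)
  expect_equal(extract_anchors(mm, "exon_intron")$pos, 299L)
  # single-exon gene yields no boundary anchors
  m1 <- gene_models("s1", "chr1", "+", list(cbind(100L, 200L)))
  expect_equal(nrow(extract_anchors(m1, "intron_exon")), 0L)
  expect_equal(nrow(extract_anchors(m1, "exon_intron")), 0L)
})

test_that("anchor counts match the number of internal edges", {
  m <- toy_multi_models(6L, k = 5L)
  n_edges <- sum(pmax(vapply(m$exons, nrow, integer(1)) - 1L, 0L))
  expect_equal(nrow(extract_anchors(m, "intron_exon")), n_edges)
  expect_equal(nrow(extract_anchors(m, "exon_intron")), n_edges)
  expect_equal(nrow(extract_anchors(m, "tss")), nrow(m))
})

test_that("minus-strand anchors mirror the plus-strand gene", {
  L <- 1000L
  exons <- cbind(start = c(100L, 300L, 600L), end = c(200L, 400L, 700L))
  plus <- gene_models("g", "chr1", "+", list(exons))
  mirrored <- cbind(start = L - exons[, "end"], end = L - exons[, "start"])
  minus <- gene_models("g", "chr1", "-", list(mirrored))
  for (kind in c("tss", "intron_exon", "exon_intron")) {
    ap <- extract_anchors(plus, kind)
    am <- extract_anchors(minus, kind)
    expect_setequal(L - 1L - am$pos, ap$pos)
  }
})

test_that("exon classification partitions internal exons exhaustively", {
  m <- toy_multi_models(5L, k = 4L, tpm = c(0, 1, 5, 10, 50))
  internal <- internal_exons(m)
  expect_equal(nrow(internal), 5L * 2L)
  cass <- internal[c(1, 4), c("chrom", "start", "end", "strand", "gene_id")]
  cass$inclusion <- c(0.3, 0.8)
  rec <- classify_exons(m, cass)
  expect_equal(sum(rec$exon_class == "cassette"), 2L)
  expect_equal(sum(rec$exon_class == "constitutive"), 8L)
  expect_true(all(is.na(rec$inclusion[rec$exon_class == "constitutive"])))
  expect_true(all(!is.na(rec$inclusion[rec$exon_class == "cassette"])))
  # host-gene expression is joined
  expect_equal(rec$expression,
               m$expression[match(rec$gene_id, m$gene_id)])
  # empty cassette table: all constitutive
  rec0 <- classify_exons(m, NULL)
  expect_true(all(rec0$exon_class == "constitutive"))
  # duplicates deduplicated
  rec2 <- classify_exons(m, rbind(cass, cass[1, ]))
  expect_equal(sum(rec2$exon_class == "cassette"), 2L)
  # orphan call kept with warning
  orphan <- data.frame(chrom = "chr1", start = 99000L, end = 99100L,
                       strand = "+", gene_id = "gX", inclusion = 0.5)
  expect_warning(rec3 <- classify_exons(m, rbind(cass, orphan)),
                 "absent")
  expect_equal(sum(rec3$exon_class == "cassette"), 3L)
})

test_that("inclusion bins are right-closed with zero in the lowest bin", {
  rec <- data.frame(gene_id = "g", chrom = "chr1", start = 0L, end = 1L,
                    strand = "+", exon_index = 2L, exon_class = "cassette",
                    inclusion = c(0, 0.10, 0.40, 0.50, 0.95),
                    expression = 1)
  b <- bin_by_inclusion(rec)
  expect_equal(as.character(b$inclusion_class),
               c("very_low", "very_low", "low", "medium", "high"))
  empty <- rec[0, ]
  expect_equal(nrow(bin_by_inclusion(empty)), 0L)
  bad <- rec[1, ]; bad$inclusion <- 1.5
  expect_error(bin_by_inclusion(bad), "inclusion")
})
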