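test_that("anchored matrices are strand-oriented and NA-padded", {
  # constant track: matrix all constant
  tr <- toy_track(rep(1, 20000))
  anchors <- extract_anchors(toy_multi_models(3L), "intron_exon")
  m <- anchored_matrix(tr, anchors, 100, 100)
  expect_true(all(m == 1))
  expect_equal(ncol(m), 200L)
  # minus-strand anchor on a linear ramp reads the window reversed
  ramp <- toy_track(0:19)
  a_plus <- data.frame(kind = "tss", chrom = "chr1", pos = 10L,
                       strand = "+", gene_id = "gp", exon_index = NA)
  a_minus <- data.frame(kind = "tss", chrom = "chr1", pos = 10L,
                        strand = "-", gene_id = "gm", exon_index = NA)
  mp <- anchored_matrix(ramp, a_plus, 5, 5)
  mm <- anchored_matrix(ramp, a_minus, 5, 5)
  expect_equal(as.numeric(mp), 5:14)          # offsets -5..4 at pos 10
  expect_equal(as.numeric(mm), 15:6)          # mirrored window
  # off-chromosome padding is missing, not zero
  near <- data.frame(kind = "tss", chrom = "chr1", pos = 10L,
                     strand = "+", gene_id = "g", exon_index = NA)
  mnear <- anchored_matrix(toy_track(rep(1, 3000)), near, 1000, 10)
  expect_equal(sum(is.na(mnear)), 990L)
  expect_error(anchored_matrix(tr, a_plus[0, ], 10, 10), "empty")
})

test_that("mean profiles average non-missing rows with normal bands", {
  m <- structure(rbind(c(0, 1), c(2, 1)), offsets = 0:1,
                 anchors = data.frame(gene_id = c("a", "b")),
                 class = c("profile_matrix", "matrix"))
  pr <- mean_profile(m)
  expect_equal(pr$mean, c(1, 1))
  expect_equal(pr$lower[2], 1)   # identical rows: zero-width band
  expect_equal(pr$upper[2], 1)
  expect_true(pr$lower[1] < 1 && pr$upper[1] > 1)
  # ~95% pointwise coverage on iid normal rows
  set.seed(42)
  big <- structure(matrix(rnorm(500 * 200, mean = 5), 500),
                   offsets = seq_len(200),
                   anchors = data.frame(gene_id = as.character(1:500)),
                   class = c("profile_matrix", "matrix"))
  prb <- mean_profile(big)
  covered <- mean(prb$lower <= 5 & 5 <= prb$upper)
  expect_gt(covered, 0.88)
})

test_that("uniform coverage gives a flat profile to machine precision", {
  tr <- toy_track(rep(2.5, 30000))
  anchors <- extract_anchors(toy_multi_models(5L), "intron_exon")
  pr <- mean_profile(anchored_matrix(tr, anchors, 1000, 1000))
  expect_equal(pr$mean, rep(2.5, 2000), tolerance = 1e-12)
})

test_that("expression stratification: repressed class plus rank tertiles", {
  tpm <- c(0, 0, 1:9)
  m <- toy_multi_models(11L, tpm = tpm)
  anchors <- extract_anchors(m, "tss")
  s <- stratify_anchors(anchors, "expression",
                        expression = setNames(tpm, m$gene_id))
  expect_equal(sum(s$class == "repressed"), 2L)
  expect_equal(unname(table(s$class)[c("low", "medium", "high")]),
               rep(3L, 3), ignore_attr = TRUE)
  # deterministic tie-break by anchor order
  tpm2 <- rep(5, 6)
  m2 <- toy_multi_models(6L, tpm = tpm2)
  a2 <- extract_anchors(m2, "tss")
  s2a <- stratify_anchors(a2, "expression",
                          expression = setNames(tpm2, m2$gene_id))
  s2b <- stratify_anchors(a2, "expression",
                          expression = setNames(tpm2, m2$gene_id))
  expect_identical(s2a$class, s2b$class)
  expect_equal(as.character(s2a$class),
               rep(c("low", "medium", "high"), each = 2))
  # all repressed: single class with warning
  expect_warning(stratify_anchors(a2, "expression",
                                  expression = setNames(rep(0, 6),
                                                        m2$gene_id)),
                 "repressed")
})

test_that("signal-window scores match a brute-force window mean", {
  set.seed(11)
  v <- runif(5000)
  tr <- toy_track(v)
  anchors <- data.frame(kind = "intron_exon", chrom = "chr1",
                        pos = c(1000L, 2000L), strand = c("+", "-"),
                        gene_id = c("a", "b"), exon_index = 2L)
  sc <- anchor_window_score(tr, anchors, c(0L, 150L))
  expect_equal(sc[1], mean(v[1001:1150]))
  expect_equal(sc[2], mean(v[(2001 - 149):2001]))
})

test_that("class profiles reassemble into the pooled profile", {
  set.seed(5)
  tpm <- c(0, 0.5, 2, 8, 40, 200)
  m <- toy_multi_models(6L, tpm = tpm)
  tr <- toy_track(runif(40000))
  anchors <- stratify_anchors(extract_anchors(m, "intron_exon"),
                              "expression",
                              expression = setNames(tpm, m$gene_id))
  pm <- anchored_matrix(tr, anchors, 200, 200)
  cp <- class_profiles(pm)
  pooled <- mean_profile(pm)
  sizes <- table(anchors$class)
  recon <- vapply(split(cp, cp$offset), function(d)
    sum(d$mean * as.numeric(sizes[as.character(d$class)])) / sum(sizes),
    numeric(1L))
  expect_equal(unname(recon[as.character(pooled$offset)]), pooled$mean)
})

test_that("metagene scaling is flat for constant tracks and exact on ramps", {
  tr <- toy_track(rep(3, 10000), normalized = TRUE)
  iv <- data.frame(chrom = "chr1", start = c(100L, 900L, 5000L),
                   end = c(150L, 1040L, 5500L), strand = "+")
  mg <- metagene_scale(tr, iv, nbins = 10)
  expect_equal(mg$mean, rep(3, 10), tolerance = 1e-12)
  # linear ramp over one exon: bin means from the step-function integral
  L <- 137L
  v <- numeric(1000); v[101:(100 + L)] <- 0:(L - 1)
  rampt <- toy_track(v)
  one <- data.frame(chrom = "chr1", start = 100L, end = 100L + L,
                    strand = "+")
  mg2 <- metagene_scale(rampt, one, nbins = 10)
  # independent oracle: exact integral of the per-base step function
  oracle <- vapply(seq_len(10), function(j) {
    a <- (j - 1) * L / 10; b <- j * L / 10
    xs <- seq(floor(a), ceiling(b))
    tot <- 0
    for (k in utils::head(xs, -1)) {
      lo <- max(a, k); hi <- min(b, k + 1)
      if (hi > lo && k < L) tot <- tot + (hi - lo) * k
    }
    tot / (b - a)
  }, numeric(1))
  expect_equal(mg2$mean, oracle, tolerance = 1e-9)
  # strand orientation reverses bins
  oneneg <- transform(one, strand = "-")
  expect_equal(metagene_scale(rampt, oneneg, 10)$mean, rev(mg2$mean))
  # equal constant intervals of very different lengths contribute equally
  iv2 <- data.frame(chrom = "chr1", start = c(100L, 2000L),
                    end = c(150L, 2500L), strand = "+")
  tr2 <- toy_track(rep(7, 10000))
  expect_equal(metagene_scale(tr2, iv2, 10)$mean, rep(7, 10))
  expect_error(metagene_scale(tr, iv[0, ], 10), "empty")
})

test_that("heatmap groups partition the ranked anchors with larger first", {
  set.seed(2)
  M <- structure(matrix(runif(200 * 10), 200),
                 offsets = 1:10,
                 anchors = data.frame(gene_id = as.character(1:200)),
                 class = c("profile_matrix", "matrix"))
  key <- runif(200)
  hm <- heatmap_groups(M, key, ngroups = 100)
  expect_equal(dim(hm), c(100L, 10L))
  expect_equal(attr(hm, "sizes"), rep(2L, 100))
  # 101 anchors: first group takes the remainder
  M2 <- structure(M[1:101, ], offsets = 1:10,
                  anchors = data.frame(gene_id = as.character(1:101)),
                  class = c("profile_matrix", "matrix"))
  hm2 <- heatmap_groups(M2, key[1:101], ngroups = 100)
  expect_equal(attr(hm2, "sizes"), c(2L, rep(1L, 99)))
  # group means equal brute-force means of member rows
  ord <- order(key, seq_along(key))
  expect_equal(hm[1, ], colMeans(M[ord[1:2], , drop = FALSE]))
  expect_equal(hm[100, ], colMeans(M[ord[199:200], , drop = FALSE]))
})

test_that("mirroring the genome and flipping strands leaves profiles fixed", {
  set.seed(8)
  L <- 30000L
  v <- runif(L)
  m <- toy_multi_models(4L)
  anchors <- extract_anchors(m, "intron_exon")
  pr1 <- mean_profile(anchored_matrix(toy_track(v), anchors, 300, 300))
  flipped <- anchors
  flipped$pos <- L - 1L - anchors$pos
  flipped$strand <- ifelse(anchors$strand == "+", "-", "+")
  pr2 <- mean_profile(anchored_matrix(toy_track(rev(v)), flipped, 300, 300))
  expect_equal(pr1$mean, pr2$mean)
})
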