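make_pm <- function(M, anchors, offsets = seq_len(ncol(M)) - 1L) {
  structure(M, offsets = offsets, anchors = anchors,
            class = c("profile_matrix", "matrix"))
}

test_that("slope profile recovers an analytically forced relationship", {
  set.seed(1)
  n <- 40L; p <- 60L
  tpm <- round(exp(runif(n, 0, 6)), 3)
  anchors <- data.frame(gene_id = sprintf("g%02d", seq_len(n)))
  expr <- setNames(tpm, anchors$gene_id)
  z <- log2(tpm + 1)
  eps <- 0.1
  inputv <- 5
  # chip chosen so that (chip + eps)/(input + eps) = 0.5 + 0.3 z exactly
  chip <- matrix(rep((0.5 + 0.3 * z) * (inputv + eps) - eps, p), n, p)
  input <- matrix(inputv, n, p)
  sl <- slope_profile(make_pm(chip, anchors), make_pm(input, anchors),
                      expr, window = 20, pseudocount = eps)
  expect_equal(sl$slope, rep(0.3, p), tolerance = 1e-10)
  expect_true(all(sl$stderr < 1e-6))  # zero residual up to rounding
  # ratio independent of expression: slope 0 everywhere
  chip0 <- matrix(1 * (inputv + eps) - eps, n, p)
  sl0 <- slope_profile(make_pm(chip0, anchors), make_pm(input, anchors),
                       expr, pseudocount = eps)
  expect_equal(sl0$slope, rep(0, p), tolerance = 1e-12)
  expect_error(slope_profile(make_pm(chip[1:2, ], anchors[1:2, , drop = FALSE]),
                             make_pm(input[1:2, ], anchors[1:2, , drop = FALSE]),
                             expr), "3 anchors")
})

test_that("column-wise OLS agrees with lm, including missing entries", {
  set.seed(7)
  n <- 25L
  x <- rnorm(n)
  Y <- matrix(rnorm(n * 6), n)
  Y[sample(length(Y), 12)] <- NA
  fit <- metachrom:::ols_by_column(x, Y)
  for (j in 1:6) {
    ref <- summary(lm(Y[, j] ~ x))$coefficients
    expect_equal(fit$slope[j], ref["x", "Estimate"])
    expect_equal(fit$stderr[j], ref["x", "Std. Error"])
  }
})

test_that("slope is nearly invariant to rescaling expression", {
  set.seed(3)
  n <- 60L; p <- 10L
  tpm <- exp(runif(n, 5, 10))  # large, so log(TPM+1) ~ log(TPM)
  anchors <- data.frame(gene_id = sprintf("g%02d", seq_len(n)))
  z <- log2(tpm + 1)
  chip <- matrix(rep(1 + 0.2 * z, p), n, p) + rnorm(n * p, sd = 0.01)
  input <- matrix(2, n, p)
  s1 <- slope_profile(make_pm(chip, anchors), make_pm(input, anchors),
                      setNames(tpm, anchors$gene_id))
  s2 <- slope_profile(make_pm(chip, anchors), make_pm(input, anchors),
                      setNames(10 * tpm, anchors$gene_id))
  expect_equal(s2$slope, s1$slope, tolerance = 0.01)
})

test_that("positional correlation is 1 on identical tracks, NA on constants", {
  set.seed(4)
  n <- 50L; p <- 200L
  anchors <- data.frame(gene_id = sprintf("g%02d", seq_len(n)))
  A <- matrix(rexp(n * p), n)
  pa <- make_pm(A, anchors); pb <- make_pm(A + 0, anchors)
  pc <- positional_correlation(pa, pb, window = 50)
  expect_true(all(abs(pc$r - 1) < 1e-12))
  # symmetry and positive-scale invariance
  B <- matrix(rexp(n * p), n)
  r_ab <- positional_correlation(pa, make_pm(B, anchors), window = 50)$r
  r_ba <- positional_correlation(make_pm(B, anchors), pa, window = 50)$r
  expect_equal(r_ab, r_ba)
  r_scaled <- positional_correlation(pa, make_pm(3 * B, anchors),
                                     window = 50)$r
  expect_equal(r_scaled, r_ab, tolerance = 0.02)
  # constant window in one track: missing
  C <- matrix(1, n, p)
  expect_true(all(is.na(
    positional_correlation(pa, make_pm(C, anchors), window = 50)$r)))
})

test_that("independent tracks show near-zero correlation at most positions", {
  set.seed(12)
  n <- 500L; p <- 1000L
  anchors <- data.frame(gene_id = sprintf("g%03d", seq_len(n)))
  A <- matrix(rexp(n * p), n); B <- matrix(rexp(n * p), n)
  pc <- positional_correlation(make_pm(A, anchors), make_pm(B, anchors),
                               window = 50)
  expect_gte(mean(abs(pc$r) < 0.1), 0.95)
})

test_that("matched subsampling reproduces the target expression profile", {
  # identical expression values: per-bin counts match exactly
  target <- data.frame(gene_id = letters[1:10],
                       expression = c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512))
  pool <- rbind(target, target, target)
  pool$gene_id <- paste0(pool$gene_id, seq_len(nrow(pool)))
  sub <- matched_subsample(pool, target, nbins = 5, seed = 1)
  expect_equal(nrow(sub), nrow(target))
  br <- c(-Inf, quantile(log2(target$expression + 1), c(.2, .4, .6, .8)), Inf)
  expect_equal(table(cut(log2(sub$expression + 1), br)),
               table(cut(log2(target$expression + 1), br)))
  # determinism contract
  s1 <- matched_subsample(pool, target, seed = 7)
  s2 <- matched_subsample(pool, target, seed = 7)
  s3 <- matched_subsample(pool, target, seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1$gene_id, s3$gene_id))
  # no duplicates, subset of pool
  expect_equal(anyDuplicated(rownames(s1)), 0L)
  expect_true(all(s1$gene_id %in% pool$gene_id))
  expect_error(matched_subsample(target, pool, seed = 1), "smaller")
})

test_that("subsampling a skewed pool matches the target distribution", {
  set.seed(21)
  target <- data.frame(gene_id = sprintf("t%03d", 1:500),
                       expression = rlnorm(500, 1, 1))
  pool <- data.frame(gene_id = sprintf("p%04d", 1:5000),
                     expression = rlnorm(5000, 2.5, 1.2))
  sub <- suppressWarnings(matched_subsample(pool, target, nbins = 20,
                                            seed = 2))
  expect_equal(nrow(sub), 500L)
  ks <- suppressWarnings(
    ks.test(log2(sub$expression + 1), log2(target$expression + 1)))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("window mean comparison computes group means and a Welch test", {
  v <- numeric(4000)
  set.seed(31)
  # regions with known per-region means
  ra <- data.frame(chrom = "chr1", start = seq(0L, 1900L, 100L),
                   end = seq(50L, 1950L, 100L))
  rb <- data.frame(chrom = "chr1", start = seq(2000L, 3900L, 100L),
                   end = seq(2050L, 3950L, 100L))
  ma <- rnorm(nrow(ra), 20, 2); mb <- rnorm(nrow(rb), 13, 2)
  for (i in seq_len(nrow(ra))) v[(ra$start[i] + 1):ra$end[i]] <- ma[i]
  for (i in seq_len(nrow(rb))) v[(rb$start[i] + 1):rb$end[i]] <- mb[i]
  tr <- toy_track(v, normalized = FALSE, library_size = 1)
  out <- window_mean_compare(tr, ra, rb)
  expect_equal(out$meanA, mean(ma))
  expect_equal(out$meanB, mean(mb))
  expect_lt(out$p, 1e-3)
  ref <- t.test(ma, mb)
  expect_equal(out$p, ref$p.value)
  # identical sets: equal means, p ~ 1
  same <- window_mean_compare(tr, ra, ra)
  expect_equal(same$meanA, same$meanB)
  expect_gt(same$p, 0.999)
  expect_error(window_mean_compare(tr, ra[1, ], rb), "2 regions")
  # wilcoxon alternative available
  expect_lt(window_mean_compare(tr, ra, rb, test = "wilcoxon")$p, 1e-3)
})

test_that("positional GSEA flags a planted top-coverage set", {
  set.seed(41)
  n <- 100L; p <- 200L
  anchors <- data.frame(gene_id = sprintf("g%03d", seq_len(n)))
  M <- matrix(rexp(n * p), n)
  m <- make_pm(M, anchors, offsets = seq_len(p) - 100L)
  score <- rowMeans(M[, 100:149])
  topset <- anchors$gene_id[order(-score)[1:10]]
  sets <- list(planted = topset,
               random = sample(anchors$gene_id, 10))
  res <- positional_gsea(m, sets, window = 50)
  planted <- res[res$set == "planted", ]
  best <- planted[which.min(planted$p), ]
  # the planted set attains an extreme rank-sum p at its scoring window
  expect_lt(best$p, 1e-5)
  expect_lt(abs(best$offset - 25), 51)
  expect_true(all(res$q >= res$p))
  expect_error(positional_gsea(m, list(), window = 50), "no gene sets")
  expect_warning(positional_gsea(m, c(sets, list(tiny = "g001")),
                                 window = 50), "skipping")
})

test_that("GSEA p-values are uniform under a random gene set", {
  set.seed(51)
  n <- 100L; p <- 10000L
  anchors <- data.frame(gene_id = sprintf("g%03d", seq_len(n)))
  M <- matrix(rnorm(n * p), n)
  m <- make_pm(M, anchors, offsets = seq_len(p) - 1L)
  res <- positional_gsea(m, list(rand = sample(anchors$gene_id, 20)),
                         window = 50)
  expect_equal(nrow(res), 200L)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})
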