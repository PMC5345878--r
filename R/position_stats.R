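#' Sliding-window mean along profile offsets
#'
#' Centered running mean of width `window` across the offset (column)
#' axis, truncated (not padded) at the matrix edges; `NA` entries are
#' excluded from each window mean.
#'
#' @param matrix numeric matrix (anchors x offsets).
#' @param window window width in bp.
#' @return matrix of the same dimensions.
#' @keywords internal
window_smooth <- function(matrix, window) {
  w <- as.integer(window)
  if (w <= 1L) return(matrix)
  p <- ncol(matrix)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w %/% 2L
  M0 <- matrix
  M0[is.na(M0)] <- 0
  W <- !is.na(matrix)
  cs_v <- cbind(0, t(apply(M0, 1L, cumsum)))
  cs_w <- cbind(0, t(apply(W, 1L, cumsum)))
  lo <- pmax(seq_len(p) - half_lo, 1L)
  hi <- pmin(seq_len(p) + half_hi, p)
  sums <- cs_v[, hi + 1L, drop = FALSE] - cs_v[, lo, drop = FALSE]
  cnts <- cs_w[, hi + 1L, drop = FALSE] - cs_w[, lo, drop = FALSE]
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  out
}

#' Per-base slope of the ChIP/input ratio versus log expression
#'
#' At each offset around the anchors, the ChIP/input ratio is formed from
#' the mean RPM in a sliding `window`-bp window around that base (with a
#' pseudocount added to numerator and denominator) and an ordinary
#' least-squares line is fitted across anchors to
#' `ratio ~ log(TPM + 1)` (base `logbase`). The fitted slope and its
#' standard error are returned per offset. A positive slope at an offset
#' means signal there is gained, relative to input, as genes are more
#' highly expressed.
#'
#' @param chip,input `profile_matrix` objects sharing anchors and offsets
#'   (RPM scale).
#' @param expression named numeric vector of per-gene TPM.
#' @param window sliding window width in bp (default 20).
#' @param pseudocount added to both ratio terms (default 0.1 RPM).
#' @param logbase logarithm base for expression (default 2).
#' @return data.frame with columns `offset`, `slope`, `stderr`, `n`;
#'   attribute `"params"` records the window, pseudocount and log base.
#' @export
slope_profile <- function(chip, input, expression, window = 20L,
                          pseudocount = 0.1, logbase = 2) {
  anc <- attr(chip, "anchors")
  if (!identical(dim(chip), dim(input)))
    stop("chip and input matrices must share anchors and offsets")
  if (nrow(chip) < 3L) stop("need at least 3 anchors")
  tpm <- unname(expression[anc$gene_id])
  if (anyNA(tpm)) stop("missing expression for some anchor genes")
  x <- log(tpm + 1, base = logbase)
  if (stats::var(x) == 0) stop("zero-variance expression")
  ratio <- (window_smooth(chip, window) + pseudocount) /
           (window_smooth(input, window) + pseudocount)
  fit <- ols_by_column(x, ratio)
  out <- data.frame(offset = attr(chip, "offsets"), slope = fit$slope,
                    stderr = fit$stderr, n = fit$n, row.names = NULL)
  attr(out, "params") <- list(window = window, pseudocount = pseudocount,
                              logbase = logbase)
  out
}

#' Column-wise simple OLS via normal equations
#'
#' Fits `y ~ x` independently for every column of `Y`, excluding `NA`
#' entries per column.
#'
#' @param x predictor vector (length `nrow(Y)`).
#' @param Y response matrix.
#' @return list with vectors `slope`, `stderr`, `intercept`, `n`.
#' @keywords internal
ols_by_column <- function(x, Y) {
  W <- !is.na(Y)
  Y0 <- Y
  Y0[!W] <- 0
  n <- colSums(W)
  Sx <- as.numeric(crossprod(W, x))
  Sxx <- as.numeric(crossprod(W, x * x))
  Sy <- colSums(Y0)
  Sxy <- as.numeric(crossprod(Y0, x))
  Syy <- colSums(Y0 * Y0)
  Sxx_c <- Sxx - Sx^2 / n
  Sxy_c <- Sxy - Sx * Sy / n
  Syy_c <- Syy - Sy^2 / n
  slope <- Sxy_c / Sxx_c
  intercept <- Sy / n - slope * Sx / n
  rss <- pmax(Syy_c - slope * Sxy_c, 0)
  s2 <- rss / (n - 2L)
  stderr <- sqrt(s2 / Sxx_c)
  bad <- n < 3L | Sxx_c <= 0
  slope[bad] <- NA_real_; stderr[bad] <- NA_real_; intercept[bad] <- NA_real_
  list(slope = slope, stderr = stderr, intercept = intercept, n = n)
}

#' Positional Pearson correlation between two tracks
#'
#' For each window position tiling the flank, the per-anchor mean
#' coverage in a fixed `window`-bp window is computed for each track,
#' log-transformed with a pseudocount, and the Pearson correlation across
#' anchors is reported. Windows where either vector is constant yield
#' `NA`.
#'
#' @param a,b `profile_matrix` objects sharing anchors and offsets.
#' @param window window size in bp (default 50).
#' @param step distance between successive window starts (default
#'   `window`, i.e. non-overlapping tiling).
#' @param pseudocount added before the log transform (default 0.1).
#' @param logbase logarithm base (default 2).
#' @return data.frame with `offset` (window center), `r`, `n`.
#' @export
positional_correlation <- function(a, b, window = 50L, step = window,
                                   pseudocount = 0.1, logbase = 2) {
  if (!identical(dim(a), dim(b)))
    stop("matrices must share anchors and offsets")
  off <- attr(a, "offsets")
  window <- as.integer(window); step <- as.integer(step)
  starts <- seq.int(off[1L], off[length(off)] - window + 1L, by = step)
  res <- lapply(starts, function(s) {
    cols <- which(off >= s & off < s + window)
    ma <- rowMeans(a[, cols, drop = FALSE], na.rm = FALSE)
    mb <- rowMeans(b[, cols, drop = FALSE], na.rm = FALSE)
    ok <- !is.na(ma) & !is.na(mb)
    la <- log(ma[ok] + pseudocount, base = logbase)
    lb <- log(mb[ok] + pseudocount, base = logbase)
    r <- if (sum(ok) < 3L || stats::sd(la) == 0 || stats::sd(lb) == 0)
      NA_real_ else stats::cor(la, lb)
    data.frame(offset = s + (window %/% 2L), r = r, n = sum(ok))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "params") <- list(window = window, step = step,
                              pseudocount = pseudocount, logbase = logbase)
  out
}

#' Expression-matched subsampling of a pool of exons
#'
#' Draws, without replacement, a subset of the (larger) pool whose
#' log-expression distribution matches the target set: the target's
#' `log2(TPM + 1)` values are split into `nbins` quantile bins and the
#' same number of pool records is sampled from each bin. If a bin has too
#' few pool records the shortfall is borrowed from the nearest bins (with
#' a warning). The subset size always equals the target size.
#'
#' @param pool,target exon-record data.frames with an `expression` column.
#' @param nbins number of quantile bins (default 20).
#' @param seed integer seed making the draw reproducible.
#' @return the sampled subset of `pool` rows.
#' @export
matched_subsample <- function(pool, target, nbins = 20L, seed) {
  if (nrow(pool) < nrow(target))
    stop("pool smaller than target (", nrow(pool), " < ", nrow(target), ")")
  if (missing(seed)) stop("seed is required")
  lt <- log2(target$expression + 1)
  lp <- log2(pool$expression + 1)
  qs <- stats::quantile(lt, probs = seq(0, 1, length.out = nbins + 1L),
                        type = 7)
  qs[1L] <- -Inf; qs[length(qs)] <- Inf
  qs <- unique(qs)
  nb <- length(qs) - 1L
  bt <- cut(lt, qs, labels = FALSE, right = TRUE)
  bp <- cut(lp, qs, labels = FALSE, right = TRUE)
  need <- tabulate(bt, nbins = nb)
  avail <- tabulate(bp, nbins = nb)
  take <- pmin(need, avail)
  short <- need - take
  if (any(short > 0)) {
    warning("expression bins with shortfall; borrowing from nearest bins")
    for (b in which(short > 0)) {
      k <- short[b]
      for (dist in seq_len(nb)) {
        for (nb2 in c(b - dist, b + dist)) {
          if (k == 0L) break
          if (nb2 >= 1L && nb2 <= nb) {
            extra <- min(k, avail[nb2] - take[nb2])
            take[nb2] <- take[nb2] + extra
            k <- k - extra
          }
        }
        if (k == 0L) break
      }
      short[b] <- k
    }
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- unlist(lapply(seq_len(nb), function(b) {
    cand <- which(bp == b)
    if (take[b] == 0L) return(integer())
    cand[sample.int(length(cand), take[b])]
  }))
  pool[sort(idx), , drop = FALSE]
}

#' Compare mean coverage between two region sets
#'
#' Computes the per-region mean coverage per base for each set and tests
#' the difference of group means. The default test is Welch's two-sided
#' t-test on the per-region means; a Wilcoxon rank-sum alternative is
#' available.
#'
#' @param track a [coverage_track].
#' @param regionsA,regionsB data.frames with `chrom`, `start`, `end`
#'   (0-based half-open). Regions outside the chromosome are clipped;
#'   regions empty after clipping are dropped.
#' @param test `"welch"` or `"wilcoxon"`.
#' @return list with `meanA`, `meanB`, `p`, and the per-region mean
#'   vectors `valuesA`, `valuesB`.
#' @export
window_mean_compare <- function(track, regionsA, regionsB,
                                test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  region_means <- function(regions) {
    if (is.null(regions) || nrow(regions) == 0L) stop("empty region set")
    vapply(seq_len(nrow(regions)), function(i) {
      v <- track$values[[regions$chrom[i]]]
      if (is.null(v)) return(NA_real_)
      s <- max(regions$start[i], 0L); e <- min(regions$end[i], length(v))
      if (e <= s) return(NA_real_)
      mean(v[(s + 1L):e])
    }, numeric(1L))
  }
  va <- region_means(regionsA); va <- va[!is.na(va)]
  vb <- region_means(regionsB); vb <- vb[!is.na(vb)]
  if (length(va) < 2L || length(vb) < 2L)
    stop("need at least 2 regions per group for a test")
  p <- if (test == "welch")
    stats::t.test(va, vb)$p.value
  else
    stats::wilcox.test(va, vb, exact = FALSE)$p.value
  list(meanA = mean(va), meanB = mean(vb), p = p,
       valuesA = va, valuesB = vb)
}

#' Read gene sets from a two-column TSV or GMT file
#'
#' @param path two-column `term<TAB>gene` TSV, or GMT
#'   (`term<TAB>description<TAB>gene...`).
#' @param format `"auto"` (by extension), `"tsv"` or `"gmt"`.
#' @return named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "gmt") "gmt" else "tsv"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty gene-set file: ", path)
  if (format == "gmt") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  } else {
    tab <- utils::read.table(text = lines, sep = "\t",
                             stringsAsFactors = FALSE)
    sets <- split(tab[[2L]], tab[[1L]])
    sets <- lapply(sets, unique)
  }
  sets
}

#' Positional gene-set enrichment around the TSS
#'
#' For each fixed-size window at successive distances from the TSS, genes
#' are ranked by their mean coverage in that window and each gene set is
#' tested with a one-sided Wilcoxon rank-sum test (in-set genes having
#' higher coverage than out-of-set genes). P-values are
#' Benjamini-Hochberg adjusted across all window x set combinations.
#' Sets with fewer than `min_set` genes joined to the anchors are skipped
#' with a warning.
#'
#' @param tss_matrix a `profile_matrix` of TSS anchors (one row per gene).
#' @param gene_sets named list of character vectors (see
#'   [read_gene_sets()]).
#' @param window window size in bp (default 50).
#' @param step distance between successive window starts (default
#'   `window`).
#' @param min_set minimum joined set size (default 5).
#' @return data.frame with `offset` (window center), `set`, `statistic`
#'   (rank-biserial effect direction via the standardized rank-sum), `p`,
#'   `q`.
#' @export
positional_gsea <- function(tss_matrix, gene_sets, window = 50L,
                            step = window, min_set = 5L) {
  if (length(gene_sets) == 0L) stop("no gene sets supplied")
  anc <- attr(tss_matrix, "anchors")
  genes <- anc$gene_id
  off <- attr(tss_matrix, "offsets")
  window <- as.integer(window); step <- as.integer(step)
  keep <- vapply(gene_sets, function(s) sum(genes %in% s) >= min_set,
                 logical(1L))
  if (any(!keep))
    warning("skipping ", sum(!keep), " gene set(s) with fewer than ",
            min_set, " joined genes")
  gene_sets <- gene_sets[keep]
  if (length(gene_sets) == 0L) stop("no gene set with enough joined genes")
  starts <- seq.int(off[1L], off[length(off)] - window + 1L, by = step)
  res <- lapply(starts, function(s) {
    cols <- which(off >= s & off < s + window)
    score <- rowMeans(tss_matrix[, cols, drop = FALSE], na.rm = TRUE)
    do.call(rbind, lapply(names(gene_sets), function(nm) {
      inset <- genes %in% gene_sets[[nm]]
      wt <- stats::wilcox.test(score[inset], score[!inset],
                               alternative = "greater", exact = FALSE)
      data.frame(offset = s + (window %/% 2L), set = nm,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
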