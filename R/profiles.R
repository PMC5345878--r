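#' Anchored signal matrix
#'
#' Extracts per-base signal around a set of anchors into an anchors x
#' offsets matrix. Offsets run from `-upstream` to `downstream - 1`; for
#' minus-strand anchors the genomic window is reversed so that positive
#' offsets always point in the transcriptional (5' to 3') direction.
#' Positions falling off the chromosome are `NA` (missing), never
#' zero-filled.
#'
#' @param track a [coverage_track] (typically RPM-normalized).
#' @param anchors anchor data.frame from [extract_anchors()] (columns
#'   `chrom`, `pos`, `strand`, `gene_id`, `exon_index`).
#' @param upstream,downstream flank sizes in bp (default 1000 each).
#' @return A `profile_matrix`: numeric matrix with one row per anchor,
#'   `attr(,"offsets")` the offset of each column, and `attr(,"anchors")`
#'   the anchor table.
#' @export
anchored_matrix <- function(track, anchors, upstream = 1000L,
                            downstream = 1000L) {
  if (is.null(anchors) || nrow(anchors) == 0L) stop("empty anchor list")
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  if (upstream < 0L || downstream < 0L) stop("flank sizes must be >= 0")
  offsets <- seq.int(-upstream, downstream - 1L)
  p <- length(offsets)
  M <- matrix(NA_real_, nrow = nrow(anchors), ncol = p)
  for (ch in unique(anchors$chrom)) {
    v <- track$values[[ch]]
    if (is.null(v)) next
    rows <- which(anchors$chrom == ch)
    plus <- anchors$strand[rows] == "+"
    # genomic base index (1-based) per row/column
    idx <- outer(anchors$pos[rows], offsets,
                 FUN = function(p0, d) p0 + d) * NA
    idx[plus, ] <- outer(anchors$pos[rows][plus], offsets, `+`)
    if (any(!plus)) idx[!plus, ] <- outer(anchors$pos[rows][!plus], offsets, `-`)
    idx <- idx + 1L
    ok <- idx >= 1L & idx <= length(v)
    vals <- matrix(NA_real_, nrow = length(rows), ncol = p)
    vals[ok] <- v[idx[ok]]
    M[rows, ] <- vals
  }
  structure(M, offsets = offsets, anchors = anchors,
            class = c("profile_matrix", "matrix"))
}

#' @export
print.profile_matrix <- function(x, ...) {
  off <- attr(x, "offsets")
  cat(sprintf("<profile_matrix> %d anchors x %d offsets [%d, %d]\n",
              nrow(x), ncol(x), off[1L], off[length(off)]))
  invisible(x)
}

profile_offsets <- function(m) attr(m, "offsets")
profile_anchors <- function(m) attr(m, "anchors")

subset_profile <- function(m, rows) {
  structure(m[rows, , drop = FALSE], offsets = attr(m, "offsets"),
            anchors = attr(m, "anchors")[rows, , drop = FALSE],
            class = c("profile_matrix", "matrix"))
}

#' Mean meta-profile with pointwise 95% confidence band
#'
#' Per-offset mean over non-missing rows, with a pointwise
#' normal-approximation band `mean +/- 1.96 * sd / sqrt(n)`. Offsets where
#' every row is missing yield `NA`; offsets with a single non-missing row
#' get an `NA` band.
#'
#' @param matrix a `profile_matrix` from [anchored_matrix()].
#' @return data.frame with columns `offset`, `mean`, `lower`, `upper`, `n`.
#' @export
mean_profile <- function(matrix) {
  off <- attr(matrix, "offsets")
  n <- colSums(!is.na(matrix))
  mu <- colMeans(matrix, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  xc <- sweep(matrix, 2L, mu, `-`)
  ss <- colSums(xc * xc, na.rm = TRUE)
  sd <- sqrt(ifelse(n > 1L, ss / (n - 1L), NA_real_))
  half <- 1.96 * sd / sqrt(n)
  data.frame(offset = off, mean = mu, lower = mu - half, upper = mu + half,
             n = n, row.names = NULL)
}

#' Score anchors by mean signal in a fixed offset window
#'
#' @param track a [coverage_track].
#' @param anchors anchor data.frame.
#' @param window integer length-2 vector of offsets `[from, to)` relative
#'   to the anchor, strand-oriented.
#' @return numeric vector of per-anchor window means.
#' @export
anchor_window_score <- function(track, anchors, window) {
  m <- anchored_matrix(track, anchors, upstream = max(0L, -window[1L]),
                       downstream = max(0L, window[2L]))
  off <- attr(m, "offsets")
  cols <- off >= window[1L] & off < window[2L]
  rowMeans(m[, cols, drop = FALSE], na.rm = TRUE)
}

#' Stratify anchors into ranked classes
#'
#' Implements the ranking schemes used throughout the anchored-profile
#' analyses:
#' * `expression`: genes with TPM below `repressed_tpm` form the
#'   `repressed` class; the remaining genes are split by expression rank
#'   into equal-size tertiles `low`, `medium`, `high`.
#' * `tss_signal`: quartiles (`very_low` .. `high`) of the mean track
#'   signal in the TSS scoring window (offsets -75..-25 around the gene's
#'   TSS).
#' * `gene_body_signal`: quartiles of the mean track signal in the exon
#'   scoring window (offsets 0..+150 from the boundary anchor itself).
#'
#' Ties are broken deterministically by anchor order (first occurrence
#' ranks lower).
#'
#' @param anchors anchor data.frame.
#' @param key `"expression"`, `"tss_signal"` or `"gene_body_signal"`.
#' @param expression named numeric vector of per-gene TPM (required for
#'   `key = "expression"`).
#' @param track a [coverage_track] (required for the signal keys).
#' @param models a [gene_models] object (required for `key = "tss_signal"`
#'   to locate each anchor's TSS).
#' @param repressed_tpm TPM threshold below which a gene is `repressed`
#'   (default 0.1).
#' @param tss_window,body_window scoring windows (offset ranges).
#' @return the anchors data.frame with an ordered factor column `class`.
#' @export
stratify_anchors <- function(anchors,
                             key = c("expression", "tss_signal",
                                     "gene_body_signal"),
                             expression = NULL, track = NULL, models = NULL,
                             repressed_tpm = 0.1,
                             tss_window = c(-75L, -25L),
                             body_window = c(0L, 150L)) {
  key <- match.arg(key)
  if (key == "expression") {
    if (is.null(expression)) stop("expression values required")
    tpm <- unname(expression[anchors$gene_id])
    if (anyNA(tpm)) stop("missing expression for some anchor genes")
    cls <- rep(NA_character_, nrow(anchors))
    rep_i <- tpm < repressed_tpm
    cls[rep_i] <- "repressed"
    if (!any(!rep_i)) {
      warning("all genes repressed; single class returned")
    } else {
      i <- which(!rep_i)
      r <- rank(tpm[i], ties.method = "first")
      tert <- ceiling(3 * r / length(i))
      cls[i] <- c("low", "medium", "high")[tert]
    }
    anchors$class <- factor(cls, levels = c("repressed", "low", "medium",
                                            "high"), ordered = TRUE)
  } else {
    if (is.null(track)) stop("track required for signal-based stratification")
    if (key == "tss_signal") {
      if (is.null(models)) stop("models required for tss_signal")
      tssa <- extract_anchors(models, "tss")
      sc_gene <- anchor_window_score(track, tssa, tss_window)
      names(sc_gene) <- tssa$gene_id
      score <- unname(sc_gene[anchors$gene_id])
    } else {
      score <- anchor_window_score(track, anchors, body_window)
    }
    r <- rank(score, ties.method = "first")
    q <- ceiling(4 * r / length(r))
    anchors$class <- factor(c("very_low", "low", "medium", "high")[q],
                            levels = c("very_low", "low", "medium", "high"),
                            ordered = TRUE)
  }
  anchors
}

#' Stratified meta-profiles
#'
#' @param matrix a `profile_matrix` whose anchor table carries a `class`
#'   column (see [stratify_anchors()]).
#' @return data.frame stacking [mean_profile()] results per class, with a
#'   `class` column.
#' @export
class_profiles <- function(matrix) {
  anc <- attr(matrix, "anchors")
  if (is.null(anc$class)) stop("anchors carry no class column")
  res <- lapply(levels(anc$class), function(cl) {
    rows <- which(anc$class == cl)
    if (!length(rows)) return(NULL)
    pr <- mean_profile(subset_profile(matrix, rows))
    pr$class <- cl
    pr
  })
  out <- do.call(rbind, res)
  out$class <- factor(out$class, levels = levels(anc$class), ordered = TRUE)
  out
}

#' Metagene profile over length-scaled intervals
#'
#' Each interval is rescaled to the unit axis [0, 1] and split into
#' `nbins` equal bins; bins may span fractional bases, in which case bases
#' are weighted by their overlap with the bin. Bins are strand-oriented
#' (bin 1 is the 5' end of the feature). The profile is the unweighted
#' mean over intervals of the per-interval bin means, so intervals
#' contribute equally regardless of length.
#'
#' @param track a [coverage_track].
#' @param intervals data.frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param nbins number of bins (default 100).
#' @return data.frame with `bin`, `x` (bin midpoint on [0,1]), `mean`, `n`.
#' @export
metagene_scale <- function(track, intervals, nbins = 100L) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    stop("empty interval set")
  nbins <- as.integer(nbins)
  binmat <- matrix(NA_real_, nrow = nrow(intervals), ncol = nbins)
  for (i in seq_len(nrow(intervals))) {
    v <- track$values[[intervals$chrom[i]]]
    s <- intervals$start[i]; e <- intervals$end[i]
    if (is.null(v) || e <= s) next
    s <- max(s, 0L); e <- min(e, length(v))
    L <- e - s
    seg <- v[(s + 1L):e]
    # cumulative integral of the per-base step function at points 0..L
    cum <- c(0, cumsum(seg))
    integral_at <- function(x) {
      f <- floor(x)
      f <- pmin(pmax(f, 0), L)
      frac <- pmin(pmax(x - f, 0), 1)
      cum[f + 1L] + frac * c(seg, 0)[pmin(f + 1L, L) ]
    }
    edges <- seq(0, L, length.out = nbins + 1L)
    ints <- integral_at(edges)
    means <- diff(ints) / diff(edges)
    if (intervals$strand[i] == "-") means <- rev(means)
    binmat[i, ] <- means
  }
  ok <- rowSums(is.na(binmat)) == 0L
  data.frame(bin = seq_len(nbins),
             x = (seq_len(nbins) - 0.5) / nbins,
             mean = colMeans(binmat[ok, , drop = FALSE]),
             n = sum(ok), row.names = NULL)
}

#' Rank-grouped heatmap matrix
#'
#' Ranks anchors by a key, partitions the ranked list into `ngroups`
#' contiguous groups (sizes differing by at most one, earlier groups
#' taking the remainder), and returns per-group mean rows.
#'
#' @param matrix a `profile_matrix`.
#' @param key numeric vector, one value per anchor (e.g. expression);
#'   anchors are ranked in increasing order of `key`, so the last row of
#'   the result is the highest-key group.
#' @param ngroups number of groups (default 100; reduced to the anchor
#'   count if fewer anchors).
#' @return numeric matrix `ngroups x offsets` with attribute `"offsets"`;
#'   rows ordered from lowest to highest key.
#' @export
heatmap_groups <- function(matrix, key, ngroups = 100L) {
  n <- nrow(matrix)
  stopifnot(length(key) == n)
  ngroups <- min(as.integer(ngroups), n)
  ord <- order(key, seq_len(n))  # deterministic tie-break by anchor order
  base <- n %/% ngroups
  extra <- n %% ngroups
  sizes <- rep(base, ngroups) + c(rep(1L, extra), rep(0L, ngroups - extra))
  grp <- rep(seq_len(ngroups), times = sizes)
  out <- matrix(NA_real_, nrow = ngroups, ncol = ncol(matrix))
  for (g in seq_len(ngroups)) {
    rows <- ord[grp == g]
    out[g, ] <- colMeans(matrix[rows, , drop = FALSE], na.rm = TRUE)
  }
  attr(out, "offsets") <- attr(matrix, "offsets")
  attr(out, "sizes") <- sizes
  out
}
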