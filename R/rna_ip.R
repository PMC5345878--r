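#' Subtract a control track from a signal track
#'
#' Per-base difference of two RPM-normalized tracks, clipped at zero so
#' the result remains a valid coverage-like track (background RNA present
#' in the control library is removed; positions where the control exceeds
#' the signal become zero rather than negative).
#'
#' @param signal,control RPM-normalized [coverage_track] objects over the
#'   same chromosome universe.
#' @return A [coverage_track] (normalized) with
#'   `value = max(signal - control, 0)` at every base; `library_size` is
#'   inherited from the signal track.
#' @export
subtract_control <- function(signal, control) {
  if (!signal$normalized || !control$normalized)
    stop("both tracks must be RPM-normalized before subtraction")
  if (!setequal(names(signal$values), names(control$values)))
    stop("tracks cover different chromosome universes")
  values <- lapply(names(signal$values), function(ch) {
    pmax(signal$values[[ch]] - control$values[[ch]], 0)
  })
  names(values) <- names(signal$values)
  coverage_track(values, library_size = signal$library_size,
                 normalized = TRUE)
}

#' Boundary-anchored RNA-IP profile with peak reporting
#'
#' Aggregates a (typically control-subtracted) RNA-IP track around
#' intron-exon or exon-intron boundary anchors, optionally stratified by
#' host-gene expression, and reports the offset of the profile maximum on
#' the exonic side of the boundary. For `intron_exon` anchors the exon
#' lies at positive offsets; for `exon_intron` anchors it lies at
#' negative offsets, and the reported peak distance is the absolute
#' distance from the boundary in both cases.
#'
#' @param track a [coverage_track] (e.g. from [subtract_control()]).
#' @param anchors boundary anchors from [extract_anchors()] (one kind).
#' @param expression optional named TPM vector; when given, profiles are
#'   also stratified into expression classes via [stratify_anchors()].
#' @param upstream,downstream flank sizes in bp.
#' @param peak_search_bp how far into the exon to search for the peak
#'   (default 300).
#' @return list with `profile` (overall [mean_profile()]),
#'   `by_class` (stratified profiles or `NULL`), `peak_offset` (signed
#'   offset of the exonic maximum) and `peak_distance` (absolute distance
#'   from the boundary, bp).
#' @export
rnaip_boundary_profile <- function(track, anchors, expression = NULL,
                                   upstream = 1000L, downstream = 1000L,
                                   peak_search_bp = 300L) {
  kind <- unique(anchors$kind)
  if (length(kind) != 1L)
    stop("anchors must be of a single kind")
  m <- anchored_matrix(track, anchors, upstream, downstream)
  pr <- mean_profile(m)
  exonic <- if (kind == "exon_intron")
    pr$offset < 0L & pr$offset >= -peak_search_bp
  else
    pr$offset >= 0L & pr$offset < peak_search_bp
  sub <- pr[exonic & !is.na(pr$mean), , drop = FALSE]
  peak_offset <- sub$offset[which.max(sub$mean)]
  by_class <- NULL
  if (!is.null(expression)) {
    anc2 <- stratify_anchors(anchors, "expression", expression = expression)
    m2 <- m
    attr(m2, "anchors") <- anc2
    by_class <- class_profiles(m2)
  }
  list(profile = pr, by_class = by_class, peak_offset = peak_offset,
       peak_distance = abs(peak_offset))
}

#' Fraction of ChIP signal covered by qualifying RNA-IP bases
#'
#' Bases inside the given regions whose RNA-IP raw coverage is at least
#' `min_cov` reads qualify as RNA-IP-covered. In the default `"base"`
#' mode the function returns the fraction of ChIP fragment-bases (within
#' the regions) that fall on qualifying bases; in `"fragment"` mode it
#' returns the fraction of ChIP fragments overlapping at least one
#' qualifying base.
#'
#' @param rnaip a raw-count [coverage_track] of the RNA-IP library.
#' @param chip_fragments data.frame of ChIP fragments (`chrom`, `start`,
#'   `end`).
#' @param regions data.frame of regions (`chrom`, `start`, `end`),
#'   typically gene bodies plus promoters (1 kb upstream of the TSS).
#' @param min_cov minimum RNA-IP reads per base (default 30).
#' @param mode `"base"` or `"fragment"`.
#' @return fraction in [0, 1].
#' @export
overlap_fraction <- function(rnaip, chip_fragments, regions, min_cov = 30,
                             mode = c("base", "fragment")) {
  mode <- match.arg(mode)
  if (is.null(regions) || nrow(regions) == 0L) stop("empty region set")
  chroms <- names(rnaip$values)
  region_mask <- lapply(chroms, function(ch) {
    msk <- logical(length(rnaip$values[[ch]]))
    rg <- regions[regions$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(rg))) {
      s <- max(rg$start[i], 0L); e <- min(rg$end[i], length(msk))
      if (e > s) msk[(s + 1L):e] <- TRUE
    }
    msk
  })
  names(region_mask) <- chroms
  qualify <- lapply(chroms, function(ch)
    region_mask[[ch]] & rnaip$values[[ch]] >= min_cov)
  names(qualify) <- chroms
  if (mode == "base") {
    num <- 0; den <- 0
    chip_cov <- compute_coverage(chip_fragments,
                                 stats::setNames(
                                   vapply(rnaip$values, length, integer(1L)),
                                   chroms))
    for (ch in chroms) {
      v <- chip_cov$values[[ch]]
      den <- den + sum(v[region_mask[[ch]]])
      num <- num + sum(v[qualify[[ch]]])
    }
    if (den == 0) stop("no ChIP fragment bases within regions")
    num / den
  } else {
    fr <- chip_fragments[chip_fragments$chrom %in% chroms, , drop = FALSE]
    hits <- logical(nrow(fr))
    inreg <- logical(nrow(fr))
    for (ch in chroms) {
      i <- which(fr$chrom == ch)
      if (!length(i)) next
      q <- qualify[[ch]]; msk <- region_mask[[ch]]
      cq <- c(0L, cumsum(q)); cm <- c(0L, cumsum(msk))
      s <- pmax(fr$start[i], 0L); e <- pmin(fr$end[i], length(q))
      ok <- e > s
      hits[i[ok]] <- (cq[e[ok] + 1L] - cq[s[ok] + 1L]) > 0L
      inreg[i[ok]] <- (cm[e[ok] + 1L] - cm[s[ok] + 1L]) > 0L
    }
    if (!any(inreg)) stop("no ChIP fragments within regions")
    sum(hits & inreg) / sum(inreg)
  }
}

#' Gene-body plus promoter regions
#'
#' Builds the region set used for the RNA-IP/ChIP overlap: each gene's
#' span from first to last exon, extended by `promoter_bp` upstream of
#' the TSS (strand-aware).
#'
#' @param models a [gene_models] object.
#' @param promoter_bp promoter extension upstream of the TSS
#'   (default 1000).
#' @return data.frame with `chrom`, `start`, `end`, `gene_id`.
#' @export
gene_body_regions <- function(models, promoter_bp = 1000L) {
  start <- vapply(models$exons, function(e) e[1L, 1L], integer(1L))
  end <- vapply(models$exons, function(e) e[nrow(e), 2L], integer(1L))
  plus <- models$strand == "+"
  data.frame(chrom = models$chrom,
             start = as.integer(ifelse(plus, pmax(start - promoter_bp, 0L),
                                       start)),
             end = as.integer(ifelse(plus, end, end + promoter_bp)),
             gene_id = models$gene_id, stringsAsFactors = FALSE)
}
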