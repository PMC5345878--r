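#' Run code under a local, restorable RNG seed
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulation configuration
#'
#' Parameters of the synthetic chromatin experiment. The genome carries
#' non-overlapping multi-exon genes whose internal exons host positioned
#' nucleosomes flanked by depleted linkers. Input (total nucleosome)
#' occupancy of an exon decreases with expression; the variant track is
#' parameterised on the ChIP/input *ratio* scale: the expected measured
#' ratio at an exonic (intronic) evaluation band is
#' `ratio_o0 + beta_exon * log2(TPM+1)` (`beta_intron` for introns).
#' Because the fitted slope operates on fragment-smoothed, window-averaged
#' RPM ratios, per-base intensities are back-calculated through the
#' smoothing kernel (fragment-length box x centre jitter x analysis
#' window) so the configured slopes are recovered by the estimator in
#' expectation. The variant additionally has a TSS-proximal nucleosome at
#' -50 bp whose amplitude grows with expression, and is excluded from the
#' +1 nucleosome (~225 bp downstream of the TSS, modelled as the
#' footprint 150-300 bp). RNA-IP (CLIP) reads are exon-restricted with a
#' density peak 65 bp inside the exon from the intron-exon boundary
#' (proportionally closer for short exons) and a read rate proportional
#' to TPM.
#'
#' @param n_genes number of genes (default 300).
#' @param beta_exon,beta_intron target ChIP/input ratio slopes versus
#'   log2(TPM+1) at exonic / intronic evaluation bands (defaults 0.4 and
#'   0.1).
#' @param ratio_o0 ratio intercept (default 0.8).
#' @param input_beta slope of input exonic-nucleosome occupancy versus
#'   log2(TPM+1) (default -0.25; occupancy is lost on activation).
#' @param tss_beta variant TSS-nucleosome amplitude slope versus
#'   log2(TPM+1) (default 1.7); `tss_o0` its expression-independent part.
#' @param kappa coupling between cassette-exon inclusion and variant exon
#'   occupancy: the exon amplitude is scaled by
#'   `1 + kappa * (inclusion - 0.5)` (default 0, uncoupled).
#' @param cassette_fraction fraction of internal exons that are cassette
#'   (default 0.134).
#' @param depth_variant,depth_input,depth_control expected fragments per
#'   ChIP library (default 5e5).
#' @param clip_depth,clip_control_depth expected RNA-IP reads (defaults
#'   1e5 and 2e4).
#' @param ... further parameters; see the function definition for the
#'   complete list and defaults (fragment geometry, exon/intron length
#'   distributions, NDR geometry, expression model).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 300L,
                       beta_exon = 0.4, beta_intron = 0.1, ratio_o0 = 0.8,
                       input_beta = -0.25, tss_beta = 1.7, tss_o0 = 0,
                       kappa = 0, cassette_fraction = 0.134,
                       depth_variant = 5e5, depth_input = 5e5,
                       depth_control = 5e5,
                       clip_depth = 1e5, clip_control_depth = 2e4, ...) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    # gene structure
    exon_count_range = c(3L, 8L),
    exon_len_meanlog = log(140), exon_len_sdlog = 0.25,
    exon_len_range = c(60L, 400L),
    intron_len_meanlog = log(900), intron_len_sdlog = 0.2,
    intron_len_range = c(700L, 1500L),
    gap_mean = 1200, margin = 1500L,
    # expression model
    frac_repressed = 0.25, tpm_meanlog = log(20), tpm_sdlog = 1.2,
    # splicing
    cassette_fraction = cassette_fraction,
    inclusion_shape = c(2, 2), kappa = kappa,
    # input track (total nucleosomes)
    input_o0 = 3, input_beta = input_beta, input_min = 0.3,
    intron_level = 1, background = 0.3,
    linker_width = 25L, linker_dip = 0.4, first_last_level = 2,
    promoter_nfr = 0.4, promoter_window = c(-150L, 150L),
    plus_one_level = 3, plus_one_window = c(150L, 300L),
    # variant track (ratio-parameterised)
    ratio_o0 = ratio_o0, beta_exon = beta_exon, beta_intron = beta_intron,
    shape_acceptor_dip = 0.5, shape_donor_dip = 0.8,
    exon_ramp = c(0.85, 1.15), plus_one_exclusion = 0.1,
    tss_pos = -50L, tss_o0 = tss_o0, tss_beta = tss_beta,
    # repressive-variant control track
    z_o0 = 1.8, z_beta_exon = -0.15, z_beta_intron = -0.05,
    # fragments
    frag_mean = 147, frag_sd = 15, jitter_sd = 20,
    depth_variant = depth_variant, depth_input = depth_input,
    depth_control = depth_control,
    # RNA-IP / CLIP
    clip_depth = clip_depth, clip_control_depth = clip_control_depth,
    clip_read_mean = 40, clip_read_sd = 5,
    clip_peak = 65L, clip_peak_frac = 0.46, clip_sd = 25,
    # slope-statistic geometry used for calibration
    slope_window = 20L, pseudocount = 0.1,
    eval_exon_band = 63:77, eval_intron_band = -507:-493)
  extra <- list(...)
  if (length(extra)) {
    unknown <- setdiff(names(extra), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    cfg[names(extra)] <- extra
  }
  structure(cfg, class = "sim_config")
}

#' Null simulation configuration
#'
#' All expression couplings switched off: ratio slopes, input occupancy
#' slope, TSS amplitude slope and inclusion coupling are zero (the TSS
#' nucleosome is kept at a flat amplitude). Under this configuration the
#' expected ChIP/input ratio is independent of expression at every base.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config` list.
#' @export
sim_config_null <- function(...) {
  sim_config(beta_exon = 0, beta_intron = 0, input_beta = 0,
             tss_beta = 0, tss_o0 = 4, kappa = 0, ...)
}

clampi <- function(x, lo, hi) pmin(pmax(as.integer(round(x)), lo), hi)

#' Simulate a toy genome with expression and exon classes
#'
#' Genes are laid down sequentially on a single toy chromosome with
#' randomized strands; exon and intron lengths follow the configured
#' lognormal distributions; expression is a repressed/expressed mixture;
#' internal exons are flagged cassette at the configured rate with
#' Beta-distributed inclusion.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `models` ([gene_models] with expression),
#'   `chrom_sizes`, `expression` (data.frame `gene_id`, `tpm`),
#'   `exon_records` (internal exons with `exon_class` and `inclusion`).
#' @export
simulate_genome <- function(config, seed) {
  if (config$n_genes < 1L) stop("n_genes must be >= 1")
  with_local_seed(seed, {
    n <- config$n_genes
    cursor <- config$margin
    exons_list <- vector("list", n)
    strands <- character(n)
    for (i in seq_len(n)) {
      k <- sample(seq(config$exon_count_range[1L],
                      config$exon_count_range[2L]), 1L)
      el <- clampi(stats::rlnorm(k, config$exon_len_meanlog,
                                 config$exon_len_sdlog),
                   config$exon_len_range[1L], config$exon_len_range[2L])
      il <- clampi(stats::rlnorm(k - 1L, config$intron_len_meanlog,
                                 config$intron_len_sdlog),
                   config$intron_len_range[1L], config$intron_len_range[2L])
      starts <- cursor + cumsum(c(0L, el[-k] + il))
      exons_list[[i]] <- cbind(start = starts, end = starts + el)
      strands[i] <- sample(c("+", "-"), 1L)
      cursor <- starts[k] + el[k] +
        as.integer(round(config$gap_mean * stats::runif(1, 0.7, 1.3)))
    }
    chrom_sizes <- c(chrS1 = as.integer(cursor + config$margin))
    tpm <- ifelse(stats::runif(n) < config$frac_repressed, 0,
                  stats::rlnorm(n, config$tpm_meanlog, config$tpm_sdlog))
    ids <- sprintf("g%04d", seq_len(n))
    models <- gene_models(ids, rep("chrS1", n), strands, exons_list,
                          expression = tpm)
    rec <- internal_exons(models)
    rec$exon_class <- ifelse(stats::runif(nrow(rec)) < config$cassette_fraction,
                             "cassette", "constitutive")
    rec$inclusion <- ifelse(rec$exon_class == "cassette",
                            stats::rbeta(nrow(rec), config$inclusion_shape[1L],
                                         config$inclusion_shape[2L]),
                            NA_real_)
    rec$expression <- tpm[match(rec$gene_id, ids)]
    list(models = models, chrom_sizes = chrom_sizes,
         expression = data.frame(gene_id = ids, tpm = tpm,
                                 stringsAsFactors = FALSE),
         exon_records = rec)
  })
}

# Dense per-base fields (single toy chromosome) from which both the
# fragment sampler and the analytic expectations are computed:
#   lam_i      input fragment-centre intensity (relative units)
#   shape      variant multiplicative shape (NDR asymmetry, +1 exclusion,
#              within-exon ramp, inclusion coupling)
#   zvec       per-base log2(TPM+1) of the host gene (0 intergenic)
#   exon_ind   1 on internal-exon bases carrying the exonic ratio slope
#   intron_ind 1 on intronic bases carrying the intronic ratio slope
#   tssfield   additive variant TSS-nucleosome intensity
build_fields <- function(config, genome) {
  L <- unname(genome$chrom_sizes[1L])
  models <- genome$models
  tpmv <- models$expression
  z <- log2(tpmv + 1)
  lam_i <- rep(config$background, L)
  shape <- rep(1, L)
  zvec <- numeric(L)
  exon_ind <- numeric(L)
  intron_ind <- numeric(L)
  tssfield <- numeric(L)
  rec <- genome$exon_records
  reckey <- paste(rec$gene_id, rec$start)
  idx <- function(s, e) if (e > s) (s + 1L):e else integer()  # 0-based half-open
  for (i in seq_len(nrow(models))) {
    e <- models$exons[[i]]
    k <- nrow(e)
    gs <- e[1L, 1L]; ge <- e[k, 2L]
    strand <- models$strand[i]
    zvec[idx(gs, ge)] <- z[i]
    # introns
    for (j in seq_len(k - 1L)) {
      ii <- idx(e[j, 2L], e[j + 1L, 1L])
      lam_i[ii] <- config$intron_level
      intron_ind[ii] <- 1
    }
    # exons
    for (j in seq_len(k)) {
      ii <- idx(e[j, 1L], e[j, 2L])
      internal <- j > 1L && j < k
      if (internal) {
        lam_i[ii] <- max(config$input_o0 + config$input_beta * z[i],
                         config$input_min)
        exon_ind[ii] <- 1
        # within-exon ramp, acceptor -> donor in transcript orientation
        ramp <- seq(config$exon_ramp[1L], config$exon_ramp[2L],
                    length.out = length(ii))
        if (strand == "-") ramp <- rev(ramp)
        shape[ii] <- shape[ii] * ramp
        key <- paste(models$gene_id[i], e[j, 1L])
        r <- match(key, reckey)
        if (!is.na(r) && rec$exon_class[r] == "cassette" && config$kappa != 0)
          shape[ii] <- shape[ii] *
            max(1 + config$kappa * (rec$inclusion[r] - 0.5), 0)
        # flanking linkers: depleted in input, asymmetric in the variant
        lw <- config$linker_width
        left <- idx(max(e[j, 1L] - lw, 0L), e[j, 1L])
        right <- idx(e[j, 2L], min(e[j, 2L] + lw, L))
        lam_i[left] <- lam_i[left] * config$linker_dip
        lam_i[right] <- lam_i[right] * config$linker_dip
        acceptor <- if (strand == "+") left else right
        donor <- if (strand == "+") right else left
        shape[acceptor] <- shape[acceptor] * config$shape_acceptor_dip
        shape[donor] <- shape[donor] * config$shape_donor_dip
      } else {
        lam_i[ii] <- config$first_last_level
      }
    }
    # promoter NFR, +1 nucleosome and variant TSS kernel (strand-aware)
    tss <- models$tss[i]
    dirn <- if (strand == "+") 1L else -1L
    pw <- sort(tss + dirn * config$promoter_window)
    prom <- idx(max(pw[1L], 0L), min(pw[2L], L))
    lam_i[prom] <- config$promoter_nfr
    exon_ind[prom] <- 0; intron_ind[prom] <- 0
    p1 <- sort(tss + dirn * config$plus_one_window)
    p1i <- idx(max(p1[1L], 0L), min(p1[2L], L))
    lam_i[p1i] <- config$plus_one_level
    exon_ind[p1i] <- 0; intron_ind[p1i] <- 0
    shape[p1i] <- config$plus_one_exclusion
    tc <- tss + dirn * config$tss_pos
    half <- as.integer(config$frag_mean %/% 2)
    ti <- idx(max(tc - half, 0L), min(tc + half + 1L, L))
    tssfield[ti] <- tssfield[ti] + (config$tss_o0 + config$tss_beta * z[i])
  }
  list(lam_i = lam_i, shape = shape, zvec = zvec, exon_ind = exon_ind,
       intron_ind = intron_ind, tssfield = tssfield, z = z, L = L)
}

# Composite smoothing kernels for analytic window statistics.
# K1[t]: expected contribution of a fragment centred at offset t from the
#   window centre to the window SUM of coverage (= overlap length,
#   averaged over centre jitter). K2[t]: second moment of that overlap
#   (for the Campbell variance of the window sum).
make_kernels <- function(frag_mean, jitter_sd, window) {
  half <- frag_mean / 2
  tmax <- as.integer(ceiling(half + window / 2 + 4 * jitter_sd + 2))
  t <- (-tmax):tmax
  olen <- pmax(0, pmin(t + half, window / 2) - pmax(t - half, -window / 2))
  g <- stats::dnorm((-ceiling(4 * jitter_sd)):(ceiling(4 * jitter_sd)),
                    sd = jitter_sd)
  g <- g / sum(g)
  smooth_with <- function(v) {
    out <- stats::convolve(v, rev(g), type = "open")
    trim <- (length(out) - length(v)) %/% 2
    out[(trim + 1L):(trim + length(v))]
  }
  list(t = t, tmax = tmax, K1 = smooth_with(olen), K2 = smooth_with(olen^2))
}

# Band-averaged kernel: mean over band offsets d of K(t - d), so a single
# dot product per anchor gives the band-mean window statistic.
band_kernel <- function(kern, band) {
  t <- kern$t
  shift_vals <- band - as.integer(round(mean(band)))
  tout <- (min(t) + min(shift_vals)):(max(t) + max(shift_vals))
  acc1 <- numeric(length(tout)); acc2 <- numeric(length(tout))
  for (d in shift_vals) {
    i <- match(t + d, tout)
    acc1[i] <- acc1[i] + kern$K1
    acc2[i] <- acc2[i] + kern$K2
  }
  list(t = tout, K1 = acc1 / length(shift_vals), K2 = acc2 / length(shift_vals),
       center = as.integer(round(mean(band))))
}

# Dot product of a genome field with a kernel at oriented anchor centres.
field_dot <- function(field, centers0, plus, kern_t, kern_v) {
  vapply(seq_along(centers0), function(i) {
    p <- centers0[i] + 1L  # 1-based index of the anchor base
    offs <- if (plus[i]) kern_t else -kern_t
    sum(field[p + offs] * kern_v)
  }, numeric(1L))
}

#' Build the ground-truth object (with ratio-slope calibration)
#'
#' Computes, from the realized genome and expression, the per-base
#' intensity slopes of the variant track such that the expected fitted
#' ChIP/input ratio slope (including the first-order ratio-of-counts
#' bias at the configured sequencing depth) equals `beta_exon` at the
#' exonic evaluation band and `beta_intron` at the intronic band, over
#' the universe of all intron-exon boundary anchors.
#'
#' @param config a [sim_config()].
#' @param genome output of [simulate_genome()].
#' @return a `sim_truth` list: `config`, `genome`, calibrated
#'   coefficients (`beta_exon_base`, `beta_intron_base`), expected-slope
#'   evaluation bands, and the dense intensity fields (in `$fields`).
#' @export
build_truth <- function(config, genome) {
  f <- build_fields(config, genome)
  anchors <- extract_anchors(genome$models, "intron_exon")
  plus <- anchors$strand == "+"
  w <- config$slope_window
  kern <- make_kernels(config$frag_mean, config$jitter_sd, w)
  kb_e <- band_kernel(kern, config$eval_exon_band)
  kb_i <- band_kernel(kern, config$eval_intron_band)
  A <- f$lam_i * f$shape
  ZE <- A * f$zvec * f$exon_ind
  ZI <- A * f$zvec * f$intron_ind
  TT <- f$tssfield
  z_anchor <- log2(genome$models$expression[
    match(anchors$gene_id, genome$models$gene_id)] + 1)
  eps <- config$pseudocount
  stats_for <- function(kb) {
    ctr0 <- anchors$pos
    list(
      mi = field_dot(f$lam_i, ctr0, plus, kb$t + kb$center, kb$K1) / w,
      v2 = field_dot(f$lam_i, ctr0, plus, kb$t + kb$center, kb$K2) / w^2,
      mA = field_dot(A, ctr0, plus, kb$t + kb$center, kb$K1) / w,
      mZE = field_dot(ZE, ctr0, plus, kb$t + kb$center, kb$K1) / w,
      mZI = field_dot(ZI, ctr0, plus, kb$t + kb$center, kb$K1) / w,
      mT = field_dot(TT, ctr0, plus, kb$t + kb$center, kb$K1) / w)
  }
  st_e <- stats_for(kb_e)
  st_i <- stats_for(kb_i)
  Ti <- sum(f$lam_i)
  TA <- sum(A); TZE <- sum(ZE); TZI <- sum(ZI); Tt <- sum(TT)
  o0 <- config$ratio_o0
  Di <- config$depth_input
  ols_slope <- function(y, x) {
    xc <- x - mean(x)
    sum(xc * y) / sum(xc * xc)
  }
  expected_slope <- function(st, be, bi, Tv) {
    mu_i <- 1e6 * st$mi / Ti
    var_i <- 1e12 * st$v2 / (Di * Ti)
    Fbias <- 1 + var_i / (mu_i + eps)^2
    mu_v <- 1e6 * (o0 * st$mA + be * st$mZE + bi * st$mZI + st$mT) / Tv
    R <- (mu_v + eps) / (mu_i + eps) * Fbias
    ols_slope(R, z_anchor)
  }
  be <- config$beta_exon; bi <- config$beta_intron
  if (be != 0 || bi != 0) {
    for (it in 1:6) {
      Tv <- o0 * TA + be * TZE + bi * TZI + Tt
      s00e <- expected_slope(st_e, 0, 0, Tv)
      s10e <- expected_slope(st_e, 1, 0, Tv)
      s01e <- expected_slope(st_e, 0, 1, Tv)
      s00i <- expected_slope(st_i, 0, 0, Tv)
      s10i <- expected_slope(st_i, 1, 0, Tv)
      s01i <- expected_slope(st_i, 0, 1, Tv)
      J <- matrix(c(s10e - s00e, s01e - s00e,
                    s10i - s00i, s01i - s00i), 2L, 2L, byrow = TRUE)
      sol <- solve(J, c(config$beta_exon - s00e, config$beta_intron - s00i))
      be <- sol[1L]; bi <- sol[2L]
    }
  } else {
    be <- 0; bi <- 0
  }
  f$lam_v <- pmax(o0 * A + be * ZE + bi * ZI + TT, 0)
  f$lam_z <- pmax(f$lam_i * (config$z_o0 +
                             config$z_beta_exon * f$zvec * f$exon_ind +
                             config$z_beta_intron * f$zvec * f$intron_ind), 0)
  structure(list(config = config, genome = genome,
                 beta_exon_base = be, beta_intron_base = bi,
                 eval_exon_band = config$eval_exon_band,
                 eval_intron_band = config$eval_intron_band,
                 expected_slope_exon = config$beta_exon,
                 expected_slope_intron = config$beta_intron,
                 fields = f),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(paste0("<sim_truth> %d genes, genome %d bp; ",
                     "ratio slopes exon=%.3g intron=%.3g ",
                     "(base-level %.3g/%.3g)\n"),
              nrow(x$genome$models), x$fields$L,
              x$expected_slope_exon, x$expected_slope_intron,
              x$beta_exon_base, x$beta_intron_base))
  invisible(x)
}

# Sample fragment intervals from a per-base centre-intensity field.
sample_fragments <- function(lambda, depth, frag_mean, frag_sd, jitter_sd,
                             chrom, L) {
  total <- sum(lambda)
  if (total <= 0) {
    warning("all intensities zero; empty track")
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  n <- stats::rpois(1L, depth)
  cdf <- cumsum(lambda)
  u <- stats::runif(n) * total
  base <- findInterval(u, cdf) + 1L
  centers <- pmin(base, L) - 1L + stats::runif(n) +
    stats::rnorm(n, 0, jitter_sd)
  len <- clampi(stats::rnorm(n, frag_mean, frag_sd), 50L, 400L)
  start <- as.integer(round(centers - len / 2))
  df <- data.frame(chrom = chrom, start = start,
                   end = as.integer(start + len), stringsAsFactors = FALSE)
  df[order(df$start, df$end), , drop = FALSE]
}

#' Simulate ChIP fragments for one track
#'
#' @param truth a `sim_truth` from [build_truth()].
#' @param track `"variant"`, `"input"` or `"control_variant"`.
#' @param seed integer seed.
#' @return data.frame of fragments (`chrom`, `start`, `end`), sorted.
#' @export
simulate_fragments <- function(truth,
                               track = c("variant", "input",
                                         "control_variant"),
                               seed) {
  track <- match.arg(track)
  cfg <- truth$config
  lambda <- switch(track, variant = truth$fields$lam_v,
                   input = truth$fields$lam_i,
                   control_variant = truth$fields$lam_z)
  depth <- switch(track, variant = cfg$depth_variant,
                  input = cfg$depth_input,
                  control_variant = cfg$depth_control)
  with_local_seed(seed,
    sample_fragments(lambda, depth, cfg$frag_mean, cfg$frag_sd,
                     cfg$jitter_sd, names(truth$genome$chrom_sizes)[1L],
                     truth$fields$L))
}

#' Simulate RNA-IP (CLIP) reads and a background control library
#'
#' Signal reads are exon-restricted: each internal exon receives reads
#' at a rate proportional to host-gene TPM, centred (with Gaussian
#' scatter) at `min(clip_peak, round(clip_peak_frac * exon_length))`
#' bases inside the exon from the intron-exon boundary, and clipped to
#' the exon. The control library is a uniform low-rate background over
#' the whole genome.
#'
#' @param truth a `sim_truth`.
#' @param seed integer seed.
#' @return list with `signal` and `control` fragment data.frames.
#' @export
simulate_clip <- function(truth, seed) {
  cfg <- truth$config
  rec <- truth$genome$exon_records
  L <- truth$fields$L
  chrom <- names(truth$genome$chrom_sizes)[1L]
  with_local_seed(seed, {
    wts <- rec$expression
    if (sum(wts) <= 0) stop("no expressed genes for CLIP simulation")
    n_e <- stats::rpois(nrow(rec), cfg$clip_depth * wts / sum(wts))
    res <- lapply(which(n_e > 0L), function(r) {
      n <- n_e[r]
      s <- rec$start[r]; e <- rec$end[r]
      len_exon <- e - s
      dist <- min(cfg$clip_peak, as.integer(round(cfg$clip_peak_frac *
                                                  len_exon)))
      c0 <- if (rec$strand[r] == "+") s + dist else e - 1L - dist
      centers <- pmin(pmax(c0 + stats::rnorm(n, 0, cfg$clip_sd), s + 2L),
                      e - 2L)
      rl <- clampi(stats::rnorm(n, cfg$clip_read_mean, cfg$clip_read_sd),
                   20L, 80L)
      start <- pmax(as.integer(round(centers - rl / 2)), s)
      end <- pmin(start + rl, e)
      data.frame(chrom = chrom, start = start, end = as.integer(end),
                 stringsAsFactors = FALSE)
    })
    signal <- do.call(rbind, res)
    signal <- signal[order(signal$start, signal$end), , drop = FALSE]
    nc <- stats::rpois(1L, cfg$clip_control_depth)
    cs <- as.integer(floor(stats::runif(nc) * (L - 40L)))
    control <- data.frame(chrom = chrom, start = cs, end = cs + 40L,
                          stringsAsFactors = FALSE)
    control <- control[order(control$start), , drop = FALSE]
    list(signal = signal, control = control)
  })
}

#' Simulate a complete synthetic experiment
#'
#' Generates the genome, expression, exon classes, ground truth and all
#' fragment libraries, optionally writing every artefact to a directory
#' (BED12 gene models, chrom.sizes, expression and cassette TSVs, one
#' fragment BED per track, CLIP signal/control BEDs, and a truth JSON).
#'
#' @param config a [sim_config()].
#' @param seed integer master seed; stage seeds are derived from it.
#' @param dir optional output directory (created if missing).
#' @param tracks ChIP tracks to simulate.
#' @param clip logical; also simulate the RNA-IP libraries.
#' @return list with `genome`, `truth`, `fragments` (named list of
#'   data.frames) and `clip` (list or `NULL`).
#' @export
simulate_experiment <- function(config, seed, dir = NULL,
                                tracks = c("variant", "input",
                                           "control_variant"),
                                clip = TRUE) {
  genome <- simulate_genome(config, seed)
  truth <- build_truth(config, genome)
  fragments <- lapply(stats::setNames(seq_along(tracks), tracks),
                      function(i) simulate_fragments(truth, tracks[i],
                                                     seed + 10L + i))
  clip_out <- if (clip) simulate_clip(truth, seed + 20L) else NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bed12(genome$models, file.path(dir, "genes.bed12"))
    utils::write.table(
      data.frame(chrom = names(genome$chrom_sizes),
                 size = unname(genome$chrom_sizes)),
      file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    utils::write.table(genome$expression, file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cass <- genome$exon_records[genome$exon_records$exon_class == "cassette",
                                c("chrom", "start", "end", "strand",
                                  "gene_id", "inclusion")]
    utils::write.table(cass, file.path(dir, "cassette.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (tr in names(fragments))
      write_fragments_bed(fragments[[tr]], file.path(dir, paste0(tr, ".bed")))
    if (!is.null(clip_out)) {
      write_fragments_bed(clip_out$signal, file.path(dir, "clip_signal.bed"))
      write_fragments_bed(clip_out$control, file.path(dir, "clip_control.bed"))
    }
    jsonlite::write_json(
      list(seed = seed,
           config = truth$config[!vapply(truth$config, is.function,
                                         logical(1L))],
           beta_exon_base = truth$beta_exon_base,
           beta_intron_base = truth$beta_intron_base),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(genome = genome, truth = truth, fragments = fragments,
       clip = clip_out)
}

#' Simulate a pair of tracks with known positional correlation
#'
#' A dedicated generator for testing positional correlation recovery:
#' `n_anchors` identical exons (fixed length) are spaced along a toy
#' chromosome; the two tracks share a bivariate-lognormal exonic
#' nucleosome amplitude with latent log-scale correlation `rho_exon`,
#' while intronic 50-bp blocks get independent lognormal levels per
#' track (so the true correlation is `rho_exon` over the exon and zero
#' in the introns). Fragments are Poisson-sampled at a depth high enough
#' that log window means are dominated by the latent amplitudes.
#'
#' @param n_anchors number of exon anchors (default 500).
#' @param rho_exon latent exonic correlation (default 0.6).
#' @param seed integer seed.
#' @param exon_len exon length in bp (default 140).
#' @param spacing anchor spacing in bp (default 2400).
#' @param depth expected fragments per track (default 1.2e5).
#' @param sigma_exon,sigma_intron lognormal sd of exon / intron-block
#'   amplitudes (natural-log scale).
#' @return list with `trackA`, `trackB` (RPM [coverage_track]s),
#'   `anchors` (intron-exon anchors at the exon starts), `rho_exon`,
#'   `exon_len`.
#' @export
simulate_paired_tracks <- function(n_anchors = 500L, rho_exon = 0.6, seed,
                                   exon_len = 140L, spacing = 2400L,
                                   depth = 1.2e5, sigma_exon = 0.7,
                                   sigma_intron = 0.5) {
  with_local_seed(seed, {
    L <- as.integer(n_anchors * spacing + 2L * spacing)
    starts <- spacing + (seq_len(n_anchors) - 1L) * spacing
    lamA <- rep(0.5, L); lamB <- rep(0.5, L)
    # correlated exon amplitudes
    e1 <- stats::rnorm(n_anchors); e2 <- stats::rnorm(n_anchors)
    etaA <- e1
    etaB <- rho_exon * e1 + sqrt(1 - rho_exon^2) * e2
    block <- 50L
    for (i in seq_len(n_anchors)) {
      s <- starts[i]
      ex <- (s + 1L):(s + exon_len)
      lamA[ex] <- 4 * exp(sigma_exon * etaA[i] - sigma_exon^2 / 2)
      lamB[ex] <- 4 * exp(sigma_exon * etaB[i] - sigma_exon^2 / 2)
      for (side in c(-1L, 1L)) {
        for (b in 0:19) {
          if (side < 0L)
            ii <- (s - (b + 1L) * block + 1L):(s - b * block)
          else
            ii <- (s + exon_len + b * block + 1L):(s + exon_len +
                                                   (b + 1L) * block)
          lamA[ii] <- exp(sigma_intron * stats::rnorm(1L) -
                          sigma_intron^2 / 2)
          lamB[ii] <- exp(sigma_intron * stats::rnorm(1L) -
                          sigma_intron^2 / 2)
        }
      }
    }
    fa <- sample_fragments(lamA, depth, 147, 15, 20, "chrC1", L)
    fb <- sample_fragments(lamB, depth, 147, 15, 20, "chrC1", L)
    sizes <- c(chrC1 = L)
    ta <- normalize_rpm(compute_coverage(fa, sizes))
    tb <- normalize_rpm(compute_coverage(fb, sizes))
    anchors <- data.frame(kind = "intron_exon", chrom = "chrC1",
                          pos = as.integer(starts), strand = "+",
                          gene_id = sprintf("a%04d", seq_len(n_anchors)),
                          exon_index = 2L, stringsAsFactors = FALSE)
    list(trackA = ta, trackB = tb, anchors = anchors, rho_exon = rho_exon,
         exon_len = exon_len)
  })
}
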