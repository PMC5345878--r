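#' Coverage tracks
#'
#' A `coverage_track` stores dense per-base signal, one numeric vector per
#' chromosome, together with the number of fragments counted
#' (`library_size`) and the normalization state. Raw tracks count, at each
#' base, the number of fragments whose interval contains that base; RPM
#' tracks are raw counts scaled by `1e6 / library_size` (mean reads per
#' base pair per million reads mapped).
#'
#' @param values named list of numeric per-base vectors (one per chromosome).
#' @param library_size number of fragments counted into the track.
#' @param normalized logical; `TRUE` if values are RPM.
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(values, library_size, normalized = FALSE) {
  stopifnot(is.list(values), !is.null(names(values)))
  values <- lapply(values, as.numeric)
  if (any(vapply(values, function(v) any(v < 0), logical(1L))))
    stop("coverage values must be non-negative")
  structure(list(values = values,
                 library_size = as.numeric(library_size),
                 normalized = isTRUE(normalized),
                 units = if (isTRUE(normalized)) "RPM" else "raw"),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d chromosome(s), library_size=%g, units=%s\n",
              length(x$values), x$library_size, x$units))
  invisible(x)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with columns chromosome name and length.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  cs <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(cs$size), cs$chrom)
}

#' Read fragments from a BED file
#'
#' @param path BED file (chrom, start, end, optional name); 0-based
#'   half-open.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
read_fragments_bed <- function(path) {
  fr <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(fr)[1:3] <- c("chrom", "start", "end")
  fr[, c("chrom", "start", "end")]
}

#' Write fragments to a BED file
#'
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  utils::write.table(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert mate-interval pairs to spanning fragments
#'
#' Each properly paired read becomes one fragment spanning from the
#' leftmost mate start to the rightmost mate end. Discordant pairs (mates
#' on different chromosomes or spans exceeding `max_len`) are skipped and
#' counted. In single-end mode each read is extended to `extension` bases
#' in its read orientation.
#'
#' @param pairs data.frame with columns `chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2` (paired mode) or `chrom`, `start`, `end`,
#'   `strand` (single-end mode).
#' @param max_len maximum allowed fragment length (default 1000).
#' @param single_end logical; treat `pairs` as single-end reads.
#' @param extension fixed extension length for single-end reads
#'   (default 150).
#' @return list with `fragments` (data.frame `chrom`, `start`, `end`) and
#'   `skipped` (count of discordant pairs).
#' @export
fragments_from_pairs <- function(pairs, max_len = 1000L,
                                 single_end = FALSE, extension = 150L) {
  if (single_end) {
    plus <- pairs$strand == "+"
    start <- ifelse(plus, pairs$start, pmax(pairs$end - extension, 0L))
    end <- ifelse(plus, pairs$start + extension, pairs$end)
    return(list(fragments = data.frame(chrom = pairs$chrom,
                                       start = as.integer(start),
                                       end = as.integer(end),
                                       stringsAsFactors = FALSE),
                skipped = 0L))
  }
  start <- pmin(pairs$start1, pairs$start2)
  end <- pmax(pairs$end1, pairs$end2)
  ok <- pairs$chrom1 == pairs$chrom2 & (end - start) <= max_len & end > start
  list(fragments = data.frame(chrom = pairs$chrom1[ok],
                              start = as.integer(start[ok]),
                              end = as.integer(end[ok]),
                              stringsAsFactors = FALSE),
       skipped = sum(!ok))
}

#' Compute raw per-base coverage from fragments
#'
#' The value at base `b` is the number of fragments whose half-open
#' interval contains `b`. Fragments overhanging a chromosome end are
#' clipped, not dropped; fragments on chromosomes absent from
#' `chrom_sizes` are skipped with a warning.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return A raw [coverage_track]; `library_size` is the number of
#'   fragments counted (after removing unknown-chromosome and
#'   empty-after-clipping fragments).
#' @export
compute_coverage <- function(fragments, chrom_sizes) {
  known <- fragments$chrom %in% names(chrom_sizes)
  if (any(!known))
    warning(sum(!known), " fragment(s) on unknown chromosome(s) skipped")
  fr <- fragments[known, , drop = FALSE]
  sz <- chrom_sizes[fr$chrom]
  start <- pmax(fr$start, 0L)
  end <- pmin(fr$end, sz)
  keep <- end > start
  fr <- fr[keep, , drop = FALSE]; start <- start[keep]; end <- end[keep]
  values <- lapply(names(chrom_sizes), function(ch) {
    i <- fr$chrom == ch
    L <- chrom_sizes[[ch]]
    if (!any(i)) return(numeric(L))
    ir <- IRanges::IRanges(start = start[i] + 1L, end = end[i])
    as.numeric(IRanges::coverage(ir, width = L))
  })
  names(values) <- names(chrom_sizes)
  coverage_track(values, library_size = nrow(fr), normalized = FALSE)
}

#' Normalize a coverage track to RPM
#'
#' Scales every value by `1e6 / library_size`. Applying it to an already
#' normalized track, or to a track with zero library size, is an error.
#'
#' @param track a raw [coverage_track].
#' @return the RPM-normalized [coverage_track].
#' @export
normalize_rpm <- function(track) {
  if (track$normalized) stop("track is already RPM-normalized")
  if (track$library_size <= 0) stop("cannot normalize: library_size is 0")
  f <- 1e6 / track$library_size
  coverage_track(lapply(track$values, function(v) v * f),
                 library_size = track$library_size, normalized = TRUE)
}

#' Write a coverage track as bedGraph
#'
#' Emits maximal runs of constant value, omitting zero runs, sorted by
#' chromosome then start.
#'
#' @param track a [coverage_track].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    r <- S4Vectors::Rle(track$values[[ch]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    vals <- S4Vectors::runValue(r)
    nz <- vals != 0
    if (!any(nz)) next
    writeLines(paste(ch, starts[nz], ends[nz],
                     format(vals[nz], trim = TRUE, scientific = FALSE,
                            digits = 15),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a coverage track
#'
#' Intervals must be 0-based half-open, sorted by start within each
#' chromosome and non-overlapping; violations raise an error naming the
#' first offending data line. Bases not covered by any interval are zero.
#' The returned track carries `library_size = NA` (a bedGraph does not
#' record it) unless supplied.
#'
#' @param path bedGraph file.
#' @param chrom_sizes named integer vector; chromosomes absent from the
#'   file get all-zero vectors.
#' @param library_size optional fragment count to attach.
#' @param normalized logical; whether the values are RPM.
#' @return A [coverage_track].
#' @export
read_bedgraph <- function(path, chrom_sizes, library_size = NA_real_,
                          normalized = FALSE) {
  gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) > 1L) {
      bad <- which(start0[i][-1L] < end0[i][-length(i)])
      if (length(bad)) {
        line <- i[bad[1L] + 1L]
        if (start0[i][bad[1L] + 1L] < start0[i][bad[1L]])
          stop("bedGraph not sorted at data line ", line, " (", ch, ")")
        stop("overlapping bedGraph intervals at data line ", line, " (", ch, ")")
      }
    }
  }
  values <- lapply(names(chrom_sizes), function(ch) {
    v <- numeric(chrom_sizes[[ch]])
    i <- which(chrom == ch)
    if (length(i)) {
      s <- pmax(start0[i], 0L); e <- pmin(end0[i], chrom_sizes[[ch]])
      keep <- e > s
      s <- s[keep]; e <- e[keep]; sc <- gr$score[i][keep]
      v[sequence(e - s, from = s + 1L)] <- rep(sc, times = e - s)
    }
    v
  })
  names(values) <- names(chrom_sizes)
  coverage_track(values, library_size = library_size,
                 normalized = normalized)
}

#' Total signal in a coverage track
#'
#' @param track a [coverage_track].
#' @return the sum of all per-base values.
#' @export
track_sum <- function(track) sum(vapply(track$values, sum, numeric(1L)))
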