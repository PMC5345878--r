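#' Gene models: construction and validation
#'
#' A `gene_models` object is a data.frame with one row per gene and columns
#' `gene_id`, `chrom`, `strand` (`"+"` or `"-"`), `tss` (0-based base
#' position), an `exons` list-column (each element an integer matrix with
#' columns `start`, `end`, rows sorted, half-open genomic intervals) and an
#' optional `expression` column (TPM). All internal coordinates are 0-based
#' half-open; conversion to/from 1-based formats happens only at I/O.
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param chrom character vector of chromosome names.
#' @param strand character vector, `"+"` or `"-"`.
#' @param exons list of two-column matrices of half-open `[start, end)`
#'   exon intervals in genomic coordinates.
#' @param expression optional numeric vector of TPM values.
#' @return A `gene_models` data.frame. The TSS is derived from the exon
#'   structure: first exon start on `+`, last exon end minus one on `-`.
#' @export
gene_models <- function(gene_id, chrom, strand, exons, expression = NULL) {
  stopifnot(length(gene_id) == length(chrom),
            length(chrom) == length(strand),
            length(strand) == length(exons))
  if (anyDuplicated(gene_id))
    stop("duplicated gene_id: ", gene_id[duplicated(gene_id)][1L])
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  exons <- lapply(exons, function(e) {
    e <- matrix(as.integer(round(e)), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
    e <- e[order(e[, 1L]), , drop = FALSE]
    if (any(e[, 2L] <= e[, 1L])) stop("exon with non-positive length")
    if (nrow(e) > 1L && any(e[-1L, 1L] < e[-nrow(e), 2L]))
      stop("overlapping exons within a gene")
    e
  })
  tss <- mapply(function(e, s)
    if (s == "+") e[1L, 1L] else e[nrow(e), 2L] - 1L,
    exons, strand)
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    tss = as.integer(tss),
                    stringsAsFactors = FALSE)
  out$exons <- exons
  out$expression <- if (is.null(expression)) NA_real_ else as.numeric(expression)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  invisible(x)
}

n_exons <- function(models) vapply(models$exons, nrow, integer(1L))

#' Load gene models from GTF or BED12
#'
#' Reads an annotation file and returns one canonical transcript per gene.
#' GTF (1-based inclusive) and BED12 (0-based half-open) coordinates are
#' both normalized to 0-based half-open internally. For GTF input with
#' several transcripts per gene the canonical transcript is the one with
#' the largest total exonic length, ties broken by lexicographically
#' smallest transcript id.
#'
#' @param path annotation file path.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed12"`.
#' @return A [gene_models] object.
#' @export
load_gene_models <- function(path, format = c("auto", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed12"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gtf") "gtf" else "bed"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (format == "gtf") {
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", path)
    tx <- split(gr, gr$transcript_id)
    tx_gene <- vapply(tx, function(g) g$gene_id[1L], character(1L))
    tx_len <- vapply(tx, function(g) sum(GenomicRanges::width(g)), numeric(1L))
    keep <- vapply(split(seq_along(tx), tx_gene), function(i) {
      i <- i[order(-tx_len[i], names(tx)[i])]
      i[1L]
    }, integer(1L))
    tx <- tx[keep]
    exons <- lapply(tx, function(g) {
      cbind(start = GenomicRanges::start(g) - 1L, end = GenomicRanges::end(g))
    })
    models <- gene_models(
      gene_id = vapply(tx, function(g) g$gene_id[1L], character(1L)),
      chrom = vapply(tx, function(g)
        as.character(GenomicRanges::seqnames(g))[1L], character(1L)),
      strand = vapply(tx, function(g)
        as.character(GenomicRanges::strand(g))[1L], character(1L)),
      exons = exons)
  } else {
    if (length(gr) == 0L) stop("no gene records in ", path)
    bl <- rtracklayer::blocks(gr)
    exons <- lapply(seq_along(gr), function(i) {
      b <- bl[[i]]
      cbind(start = GenomicRanges::start(b) - 1L, end = GenomicRanges::end(b))
    })
    nm <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    models <- gene_models(
      gene_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      exons = exons)
  }
  rownames(models) <- NULL
  models
}

#' Write gene models to BED12
#'
#' @param models a [gene_models] object.
#' @param path output file path.
#' @export
write_bed12 <- function(models, path) {
  lines <- vapply(seq_len(nrow(models)), function(i) {
    e <- models$exons[[i]]
    s <- e[1L, 1L]; en <- e[nrow(e), 2L]
    paste(models$chrom[i], s, en, models$gene_id[i], 0, models$strand[i],
          s, en, "0", nrow(e),
          paste0(paste(e[, 2L] - e[, 1L], collapse = ","), ","),
          paste0(paste(e[, 1L] - s, collapse = ","), ","),
          sep = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Extract strand-oriented anchors from gene models
#'
#' Anchors mark the TSS or internal splice boundaries of each gene.
#' `intron_exon` is the splice-acceptor side of an exon (the first exonic
#' base in transcript orientation) and `exon_intron` the donor side (the
#' first intronic base). On the minus strand the biological roles swap
#' relative to genomic coordinates: an `intron_exon` anchor of a minus
#' strand exon sits at its genomic end minus one. First and last exons
#' contribute no boundary anchors (splice boundaries only exist at internal
#' edges), so single-exon genes yield none.
#'
#' @param models a [gene_models] object.
#' @param kind `"tss"`, `"intron_exon"` or `"exon_intron"`.
#' @return data.frame with columns `kind`, `chrom`, `pos` (0-based),
#'   `strand`, `gene_id`, `exon_index` (1-based index in transcript order;
#'   `NA` for TSS anchors).
#' @export
extract_anchors <- function(models,
                            kind = c("tss", "intron_exon", "exon_intron")) {
  kind <- match.arg(kind)
  if (kind == "tss") {
    out <- data.frame(kind = "tss", chrom = models$chrom, pos = models$tss,
                      strand = models$strand, gene_id = models$gene_id,
                      exon_index = NA_integer_, stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }
  res <- lapply(seq_len(nrow(models)), function(i) {
    e <- models$exons[[i]]
    n <- nrow(e)
    if (n < 2L) return(NULL)
    s <- models$strand[i]
    if (s == "+") {
      if (kind == "intron_exon") {
        pos <- e[2:n, 1L]; idx <- 2:n          # acceptor: first exonic base
      } else {
        pos <- e[1:(n - 1L), 2L]; idx <- 1:(n - 1L)  # donor: first intronic base
      }
    } else {
      # transcript order is reversed on the minus strand
      if (kind == "intron_exon") {
        pos <- e[1:(n - 1L), 2L] - 1L; idx <- n - (1:(n - 1L)) + 1L
      } else {
        pos <- e[2:n, 1L] - 1L; idx <- n - (2:n) + 1L
      }
    }
    data.frame(kind = kind, chrom = models$chrom[i], pos = as.integer(pos),
               strand = s, gene_id = models$gene_id[i],
               exon_index = as.integer(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(kind = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      gene_id = character(), exon_index = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Internal exons of each gene as a data.frame
#'
#' @param models a [gene_models] object.
#' @return data.frame with one row per internal exon: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `exon_index` (transcript order).
#' @export
internal_exons <- function(models) {
  res <- lapply(seq_len(nrow(models)), function(i) {
    e <- models$exons[[i]]
    n <- nrow(e)
    if (n < 3L) return(NULL)
    rows <- 2:(n - 1L)
    idx <- if (models$strand[i] == "+") rows else n - rows + 1L
    data.frame(gene_id = models$gene_id[i], chrom = models$chrom[i],
               start = e[rows, 1L], end = e[rows, 2L],
               strand = models$strand[i], exon_index = as.integer(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), exon_index = integer())
  rownames(out) <- NULL
  out
}

#' Classify internal exons as cassette or constitutive
#'
#' Every internal exon is labelled either cassette (with its inclusion
#' fraction) or constitutive; the partition is exhaustive and disjoint.
#' The constitutive set is the full internal-exon annotation minus the
#' cassette calls. Cassette calls absent from the annotation are kept as
#' cassette-only records with a warning. Duplicate cassette calls are
#' deduplicated (first occurrence wins).
#'
#' @param models a [gene_models] object.
#' @param cassette_calls data.frame with columns `chrom`, `start`, `end`,
#'   `strand`, `gene_id`, `inclusion` (0-based half-open coordinates), or
#'   `NULL`/empty for no cassette exons.
#' @return data.frame of exon records: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `exon_index`, `exon_class` (`"cassette"`/`"constitutive"`),
#'   `inclusion` (`NA` for constitutive), `expression` (host-gene TPM).
#' @export
classify_exons <- function(models, cassette_calls = NULL) {
  ex <- internal_exons(models)
  expr <- stats::setNames(models$expression, models$gene_id)
  ex$exon_class <- "constitutive"
  ex$inclusion <- NA_real_
  if (!is.null(cassette_calls) && nrow(cassette_calls) > 0L) {
    cc <- cassette_calls[!duplicated(cassette_calls[c("chrom", "start", "end")]), ,
                         drop = FALSE]
    key_ex <- paste(ex$chrom, ex$start, ex$end)
    key_cc <- paste(cc$chrom, cc$start, cc$end)
    hit <- match(key_cc, key_ex)
    found <- !is.na(hit)
    ex$exon_class[hit[found]] <- "cassette"
    ex$inclusion[hit[found]] <- cc$inclusion[found]
    if (any(!found)) {
      warning(sum(!found), " cassette call(s) absent from annotation; ",
              "kept as cassette-only records")
      orphan <- cc[!found, , drop = FALSE]
      ex <- rbind(ex, data.frame(
        gene_id = orphan$gene_id, chrom = orphan$chrom,
        start = orphan$start, end = orphan$end,
        strand = orphan$strand, exon_index = NA_integer_,
        exon_class = "cassette", inclusion = orphan$inclusion,
        stringsAsFactors = FALSE))
    }
  }
  ex$expression <- unname(expr[ex$gene_id])
  rownames(ex) <- NULL
  ex
}

#' Bin cassette exons by inclusion level
#'
#' Inclusion bins follow the four-class scheme used for stratified
#' inclusion profiles: very_low (0, 0.2], low (0.2, 0.4],
#' medium (0.4, 0.6], high (0.6, 1.0]; bins are right-closed and an
#' inclusion of exactly 0 falls in `very_low`.
#'
#' @param records exon-record data.frame (cassette rows; others dropped).
#' @return the cassette records with an added `inclusion_class` factor
#'   with levels `very_low < low < medium < high`.
#' @export
bin_by_inclusion <- function(records) {
  rec <- records[records$exon_class == "cassette", , drop = FALSE]
  if (nrow(rec) == 0L) {
    rec$inclusion_class <- factor(character(),
                                  levels = c("very_low", "low", "medium", "high"))
    return(rec)
  }
  if (any(rec$inclusion < 0 | rec$inclusion > 1, na.rm = TRUE))
    stop("inclusion outside [0, 1]")
  cls <- cut(rec$inclusion, breaks = c(-Inf, 0.2, 0.4, 0.6, 1.0),
             labels = c("very_low", "low", "medium", "high"), right = TRUE)
  rec$inclusion_class <- factor(cls,
                                levels = c("very_low", "low", "medium", "high"),
                                ordered = TRUE)
  rownames(rec) <- NULL
  rec
}

#' Read a cassette-call table
#'
#' Expects a TSV with columns `chrom`, `start`, `end`, `strand`,
#' `gene_id`, `inclusion` (0-based half-open coordinates).
#'
#' @param path file path.
#' @return data.frame of cassette calls.
#' @export
read_cassette_calls <- function(path) {
  cc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "inclusion")
  miss <- setdiff(need, names(cc))
  if (length(miss)) stop("cassette table missing column(s): ",
                         paste(miss, collapse = ", "))
  cc
}
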