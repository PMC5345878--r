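#' Transcripts-per-million from counts and effective lengths
#'
#' `TPM_g = 1e6 * (c_g / l_g) / sum_h (c_h / l_h)`; TPM values sum to
#' one million over all genes.
#'
#' @param counts named numeric vector of read counts.
#' @param lengths numeric vector of effective lengths in bp (same order,
#'   all positive).
#' @return data.frame with columns `gene_id`, `count`, `length`, `tpm`.
#' @export
tpm <- function(counts, lengths) {
  stopifnot(length(counts) == length(lengths))
  if (any(lengths <= 0)) stop("effective lengths must be positive")
  if (all(counts == 0)) stop("all counts are zero")
  rate <- counts / lengths
  data.frame(gene_id = if (is.null(names(counts)))
    paste0("gene", seq_along(counts)) else names(counts),
    count = as.numeric(counts), length = as.numeric(lengths),
    tpm = 1e6 * rate / sum(rate), row.names = NULL,
    stringsAsFactors = FALSE)
}

#' Read an expression table
#'
#' Accepts a TSV with a `gene_id` column plus either a `tpm` column or
#' `count` and `length` columns (in which case TPM is computed).
#'
#' @param path file path.
#' @return data.frame with at least `gene_id` and `tpm`.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(tab)) stop("expression table needs gene_id")
  if (!"tpm" %in% names(tab)) {
    if (!all(c("count", "length") %in% names(tab)))
      stop("expression table needs tpm, or count and length")
    tab <- merge(tab["gene_id"],
                 tpm(stats::setNames(tab$count, tab$gene_id), tab$length),
                 by = "gene_id", sort = FALSE)
  }
  tab
}

#' Expression vector from a table
#'
#' @param table data.frame with `gene_id` and `tpm`.
#' @return named numeric vector of TPM.
#' @export
expression_vector <- function(table) stats::setNames(table$tpm, table$gene_id)

#' Subtype fractions of a gene-family expression pool
#'
#' For a family of genes partitioned into subtypes (e.g. the H2A histone
#' family partitioned into canonical H2A, H2A.Z and a short variant),
#' reports each subtype's percentage of the family TPM total and its mean
#' TPM per gene.
#'
#' @param table expression data.frame (`gene_id`, `tpm`).
#' @param family_map named character vector mapping gene_id to subtype;
#'   genes absent from the table are an error.
#' @return data.frame with `subtype`, `n_genes`, `total_tpm`, `mean_tpm`,
#'   `percent`; percentages sum to 100.
#' @export
pool_fraction <- function(table, family_map) {
  if (length(family_map) == 0L) stop("empty family map")
  tv <- expression_vector(table)
  miss <- setdiff(names(family_map), names(tv))
  if (length(miss)) stop("genes missing from expression table: ",
                         paste(miss, collapse = ", "))
  vals <- tv[names(family_map)]
  total <- sum(vals)
  if (total <= 0) stop("family TPM total is zero")
  agg <- tapply(vals, family_map, sum)
  cnt <- tapply(vals, family_map, length)
  data.frame(subtype = names(agg), n_genes = as.integer(cnt),
             total_tpm = as.numeric(agg),
             mean_tpm = as.numeric(agg) / as.integer(cnt),
             percent = 100 * as.numeric(agg) / total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene expression ratio between two conditions
#'
#' `ratio = (TPM_A + eps) / (TPM_B + eps)`; two genes absent from either
#' table raise an error naming the gene. Two zero TPM values give a ratio
#' of 1 (eps/eps).
#'
#' @param tableA,tableB expression data.frames (`gene_id`, `tpm`).
#' @param genes character vector of genes to report.
#' @param eps pseudocount in TPM units (default 0.01).
#' @return named numeric vector of A/B ratios.
#' @export
expression_ratio <- function(tableA, tableB, genes, eps = 0.01) {
  va <- expression_vector(tableA); vb <- expression_vector(tableB)
  miss <- setdiff(genes, intersect(names(va), names(vb)))
  if (length(miss)) stop("gene(s) missing from an expression table: ",
                         paste(miss, collapse = ", "))
  stats::setNames((va[genes] + eps) / (vb[genes] + eps), genes)
}

#' qChIP relative enrichment by 2^-ddCt
#'
#' Computes, per replicate, `dCt_target = Ct_ip - Ct_input` and the same
#' for a reference amplicon measured in the same sample, then
#' `ddCt = dCt_target - dCt_ref` and `enrichment = 2^-ddCt`. The reported
#' enrichment is the mean over replicates; the standard deviation across
#' replicate enrichments is reported when there are at least 3
#' replicates. Adding any constant to all four Ct values of a replicate
#' leaves the result unchanged.
#'
#' @param measurements data.frame with columns `target_id`, `replicate`,
#'   `ct_ip`, `ct_input`, `ct_ip_ref`, `ct_input_ref`.
#' @return data.frame with `target_id`, `enrichment` (fold), `sd`
#'   (`NA` with fewer than 3 replicates), `n_replicates`.
#' @export
ddct <- function(measurements) {
  need <- c("target_id", "ct_ip", "ct_input", "ct_ip_ref", "ct_input_ref")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cts <- measurements[, c("ct_ip", "ct_input", "ct_ip_ref", "ct_input_ref")]
  if (any(!is.finite(as.matrix(cts)))) stop("non-finite Ct value")
  dd <- (measurements$ct_ip - measurements$ct_input) -
        (measurements$ct_ip_ref - measurements$ct_input_ref)
  fold <- 2^(-dd)
  res <- lapply(split(fold, measurements$target_id), function(f) {
    data.frame(enrichment = mean(f),
               sd = if (length(f) >= 3L) stats::sd(f) else NA_real_,
               n_replicates = length(f))
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(target_id = rownames(out),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Read a qChIP Ct table
#'
#' @param path TSV with columns `target_id`, `replicate`, `ct_ip`,
#'   `ct_input`, `ct_ip_ref`, `ct_input_ref`.
#' @return data.frame of measurements.
#' @export
read_qchip <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
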