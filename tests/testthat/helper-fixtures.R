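# Small fixtures and independent oracles shared across tests.

# A coverage track holding a single given per-base vector.
toy_track <- function(values, chrom = "chr1", library_size = 1e6,
                      normalized = TRUE) {
  coverage_track(stats::setNames(list(as.numeric(values)), chrom),
                 library_size = library_size, normalized = normalized)
}

# Brute-force per-base membership count: the O(N * L) coverage oracle.
brute_coverage <- function(fragments, L) {
  vapply(0:(L - 1L), function(b)
    sum(pmax(fragments$start, 0L) <= b & b < pmin(fragments$end, L)),
    numeric(1L))
}

# Random fragment instance on a toy chromosome (possibly overhanging).
random_instance <- function(seed, L = NULL, n = NULL, overhang = FALSE) {
  set.seed(seed)
  if (is.null(L)) L <- sample(200:2000, 1L)
  if (is.null(n)) n <- sample(50:500, 1L)
  lo <- if (overhang) -100L else 0L
  start <- sample(lo:(L - 10L), n, replace = TRUE)
  len <- sample(5:120, n, replace = TRUE)
  list(L = L,
       fragments = data.frame(chrom = "chr1", start = start,
                              end = start + len,
                              stringsAsFactors = FALSE))
}

# Two-exon toy gene models on a shared chromosome.
toy_two_exon_models <- function(strand = "+") {
  gene_models("gA", "chr1", strand,
              list(cbind(start = c(100L, 300L), end = c(200L, 400L))))
}

# Multi-gene toy: each gene k exons of length 100 separated by 200 bp
# introns, genes spaced out on a 100 kb chromosome.
toy_multi_models <- function(n_genes = 5L, k = 4L, strand = NULL,
                             tpm = NULL) {
  exons <- lapply(seq_len(n_genes), function(i) {
    s <- 2000L + (i - 1L) * 5000L + (seq_len(k) - 1L) * 300L
    cbind(start = s, end = s + 100L)
  })
  if (is.null(strand)) strand <- rep(c("+", "-"), length.out = n_genes)
  gene_models(sprintf("g%02d", seq_len(n_genes)), rep("chr1", n_genes),
              strand, exons, expression = tpm)
}
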