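# Shared test helpers: brute-force oracles and small fixture builders.

# Mean pairwise Hamming distance over all sample pairs, by explicit
# enumeration (independent of the column-count shortcut in window_stats).
brute_force_k <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

# Segregating-site count by direct column inspection.
brute_force_S <- function(mat) {
  sum(apply(mat, 2, function(col) length(unique(col)) > 1))
}

# Random binary haplotype matrix with a sprinkling of variant columns.
random_window <- function(n, L, p_var = 0.3) {
  mat <- matrix(0L, n, L)
  for (j in seq_len(L)) {
    if (runif(1) < p_var) {
      c_j <- sample.int(n - 1, 1)
      mat[sample.int(n, c_j), j] <- 1L
    }
  }
  mat
}

# Tajima's D by direct formula evaluation from first principles (harmonic
# sums computed inline), independent of tajima_constants/tajima_D.
direct_D <- function(k, S, n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  if (S == 0) return(0)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Write a minimal haploid VCF from explicit record lines (for toy
# fixtures); contigs is a named vector of lengths.
write_toy_vcf <- function(path, contigs, sample_names, records) {
  lines <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs)),
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_names), collapse = "\t"),
             records)
  writeLines(lines, path)
  path
}
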