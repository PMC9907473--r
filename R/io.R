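#' Write haplotype windows in ms format
#'
#' Writes a list of binary haplotype matrices (one window each, shared
#' sample size) in the classic `ms` text format: a command-style header
#' line, a seed line, then one `//` record per window with `segsites:`,
#' `positions:` (midpoints of the variant columns, as fractions of the
#' window length) and one 0/1 string per haplotype. Monomorphic columns
#' are not represented, as in `ms`.
#'
#' @param windows List of 0/1 matrices with identical row counts.
#' @param path Output file path.
#' @param L Window length in basepairs (default: `ncol` of the first
#'   window); needed to place positions.
#' @param seed Integer seed(s) recorded on the seed line (informational).
#' @return Invisibly, `path`.
#' @seealso [read_ms]
#' @export
write_ms <- function(windows, path, L = ncol(windows[[1]]), seed = 0L) {
  ns <- vapply(windows, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("all windows must share the same sample size")
  n <- ns[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("ms %d %d", n, length(windows)), con)
  writeLines(paste(seed, collapse = " "), con)
  for (w in windows) {
    counts <- colSums(w)
    poly <- which(counts > 0 & counts < n)
    writeLines("", con)
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", length(poly)), con)
    if (length(poly) > 0) {
      pos <- (poly - 0.5) / L
      writeLines(paste("positions:", paste(sprintf("%.5f", pos),
                                           collapse = " ")), con)
      writeLines(apply(w[, poly, drop = FALSE], 1, paste, collapse = ""), con)
    }
  }
  invisible(path)
}

#' Read ms-format haplotype windows
#'
#' Parses `ms`-style output (as produced by [write_ms] or by `ms` itself)
#' into a list of binary haplotype matrices of the segregating columns,
#' with the variant positions as a `"positions"` attribute (fractions of
#' the window).
#'
#' @param path Input file path.
#' @return List of integer 0/1 matrices (possibly with zero columns),
#'   each with attribute `positions`.
#' @export
read_ms <- function(path) {
  lines <- readLines(path)
  recs <- which(lines == "//")
  if (length(recs) == 0) stop("no '//' records found in ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(header[2])
  out <- vector("list", length(recs))
  bounds <- c(recs, length(lines) + 1L)
  for (r in seq_along(recs)) {
    block <- lines[(recs[r] + 1L):(bounds[r + 1L] - 1L)]
    block <- block[nzchar(block)]
    S <- as.integer(sub("^segsites:\\s*", "", block[1]))
    if (S == 0) {
      m <- matrix(0L, n, 0)
      attr(m, "positions") <- numeric(0)
    } else {
      pos <- as.numeric(strsplit(sub("^positions:\\s*", "", block[2]),
                                 "\\s+")[[1]])
      hap <- block[3:(2 + n)]
      m <- matrix(as.integer(unlist(strsplit(hap, ""), use.names = FALSE)),
                  nrow = n, ncol = S, byrow = TRUE)
      attr(m, "positions") <- pos
    }
    out[[r]] <- m
  }
  out
}

#' Write haplotype windows as a minimal VCF
#'
#' Writes one VCF 4.2 file with one contig per window (named
#' `<prefix><i>`, declared with `length = L` in the header) and haploid
#' genotypes (`GT` values `0`/`1`), positions 1-based within the window.
#' Monomorphic columns produce no records; windows with no variants
#' contribute only their contig header line. All records are `PASS` with
#' placeholder `REF=A`, `ALT=T` alleles (the model is binary
#' ancestral/derived).
#'
#' @param windows List of 0/1 matrices with identical row counts.
#' @param path Output file path.
#' @param L Window length (default `ncol` of the first window).
#' @param contig_prefix Contig name prefix (default `"win"`).
#' @return Invisibly, `path`.
#' @seealso [scan_vcf]
#' @export
write_vcf <- function(windows, path, L = ncol(windows[[1]]),
                      contig_prefix = "win") {
  ns <- vapply(windows, nrow, integer(1))
  if (length(unique(ns)) != 1)
    stop("all windows must share the same sample size")
  n <- ns[1]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=sfsmix", con)
  for (i in seq_along(windows))
    writeLines(sprintf("##contig=<ID=%s%d,length=%d>", contig_prefix, i,
                       as.integer(L)), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", paste0("hap", seq_len(n))),
                   collapse = "\t"), con)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    counts <- colSums(w)
    poly <- which(counts > 0 & counts < n)
    for (j in poly) {
      writeLines(paste(c(sprintf("%s%d", contig_prefix, i), j, ".", "A", "T",
                         ".", "PASS", ".", "GT", as.character(w[, j])),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

# Contig lengths from vcfR meta lines; NULL when none declared.
contig_lengths_from_meta <- function(meta) {
  cl <- grep("^##contig=", meta, value = TRUE)
  if (length(cl) == 0) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", cl)
  lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", cl)))
  setNames(lens, ids)
}

#' Windowed diversity statistics from a VCF
#'
#' Tiles every contig into non-overlapping windows (half-open
#' `[start, start + window)` in 0-based coordinates; VCF positions are
#' 1-based and converted on read) and computes the [window_stats]
#' quantities per window, including windows with no variants (`S = 0`,
#' `D = 0` by convention). Partial terminal windows are emitted with
#' their true length so per-site `theta_w` stays correct. Biallelic SNP
#' records only: multiallelic records are skipped with a message.
#'
#' Genotype handling: under `ploidy = "haploid"` the `GT` field must be a
#' bare allele (`0`/`1`); diploid calls are a fatal error. Under
#' `ploidy = "collapse"` (inbred-line data) homozygous diploid calls
#' collapse to one haploid allele and heterozygous calls are treated as
#' missing (counted and reported via a message). Missing genotypes are
#' handled per `missing`: `"site"` drops the affected site from the
#' window's counts; `"window"` drops the whole window (its statistics
#' become `NA`).
#'
#' @param path VCF file path (plain text or gzipped).
#' @param window Window size in basepairs, `>= 10` (default 100).
#' @param ploidy `"haploid"` or `"collapse"`; see Details.
#' @param missing `"site"` or `"window"`; see Details.
#' @return Data frame keyed by (`contig`, `start`): columns `contig`,
#'   `start` (0-based), `L`, `n`, `k`, `S`, `pi`, `theta_w`, `D`,
#'   `delta_theta_w`.
#' @export
scan_vcf <- function(path, window = 100,
                     ploidy = c("haploid", "collapse"),
                     missing = c("site", "window")) {
  ploidy <- match.arg(ploidy)
  missing <- match.arg(missing)
  if (window < 10) stop("'window' must be >= 10 bp")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("unreadable VCF '", path, "': ",
                                         conditionMessage(e)))
  lens <- contig_lengths_from_meta(v@meta)
  fix <- v@fix
  n <- ncol(v@gt) - 1L
  if (is.na(n) || n < 4) stop("VCF must contain at least 4 samples")
  has_records <- !is.null(fix) && nrow(fix) > 0
  if (has_records) {
    multi <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1 |
      nchar(fix[, "ALT"]) != 1
    if (any(multi))
      message(sprintf("skipping %d multiallelic/non-SNP record(s)", sum(multi)))
    keep <- !multi
    gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
    chrom <- fix[keep, "CHROM"]
    pos0 <- as.integer(fix[keep, "POS"]) - 1L
    if (ploidy == "haploid") {
      if (any(grepl("[/|]", gt), na.rm = TRUE))
        stop("diploid genotypes found under ploidy = 'haploid'")
      allele <- suppressWarnings(matrix(as.integer(gt), nrow(gt), ncol(gt)))
    } else {
      a <- sub("[/|].*", "", gt)
      b <- sub(".*[/|]", "", gt)
      het <- !is.na(gt) & a != b
      if (any(het))
        message(sprintf("treating %d heterozygous call(s) as missing", sum(het)))
      a[het] <- NA
      allele <- suppressWarnings(matrix(as.integer(a), nrow(gt), ncol(gt)))
    }
  } else {
    allele <- matrix(integer(0), 0, n)
    chrom <- character(0)
    pos0 <- integer(0)
  }
  if (is.null(lens)) {
    if (!has_records) stop("VCF declares no contigs and contains no records")
    lens <- tapply(pos0 + 1L, chrom, max)
    lens <- setNames(as.integer(ceiling(lens / window) * window), names(lens))
    message("no ##contig lengths declared; tiling up to the last record")
  }
  cst <- tajima_constants(n)
  out <- list()
  for (ctg in names(lens)) {
    Lc <- lens[[ctg]]
    nw <- max(1L, as.integer(ceiling(Lc / window)))
    sel <- which(chrom == ctg)
    widx <- pos0[sel] %/% window
    for (wi in seq_len(nw) - 1L) {
      Lw <- if (wi == nw - 1L) Lc - window * (nw - 1L) else window
      rows <- sel[widx == wi]
      drop_window <- FALSE
      if (length(rows) > 0) {
        sub <- allele[rows, , drop = FALSE]
        any_na <- rowSums(is.na(sub)) > 0
        if (any(any_na)) {
          if (missing == "window") drop_window <- TRUE
          sub <- sub[!any_na, , drop = FALSE]
        }
        counts <- rowSums(sub)
        poly <- counts > 0 & counts < n
        S <- sum(poly)
        k <- sum(counts[poly] * (n - counts[poly])) / (n * (n - 1) / 2)
      } else {
        S <- 0L; k <- 0
      }
      st <- if (drop_window) {
        list(k = NA_real_, S = NA_real_, pi = NA_real_, theta_w = NA_real_,
             D = NA_real_, delta_theta_w = NA_real_)
      } else {
        window_stats_from_kS(k, S, n, Lw, cst)
      }
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = wi * window, L = Lw, n = n,
        k = st$k, S = st$S, pi = st$pi, theta_w = st$theta_w, D = st$D,
        delta_theta_w = st$delta_theta_w)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
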