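#' Pairwise genotype r-squared
#'
#' Squared Pearson correlation of two dosage vectors (composite LD: no
#' phasing, genotype dosages only), computed over subjects non-missing at
#' both SNPs.  If either vector is constant on the shared support the
#' correlation is undefined and r-squared is reported as 0 (such a pair
#' can never exceed a pruning threshold).
#'
#' @param dosages_a,dosages_b Equal-length numeric vectors in `{0,1,2,NA}`.
#' @return A single r-squared value in \[0, 1\].
#' @export
#' @examples
#' pairwise_r2(c(0, 1, 2, 0, 1, 2), c(0, 0, 1, 1, 2, 2))  # 0.25
pairwise_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) {
    abort("dosage vectors must have equal length")
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  if (sum(ok) < 2) abort("fewer than 2 subjects non-missing at both SNPs")
  a <- dosages_a[ok]
  b <- dosages_b[ok]
  if (var(a) == 0 || var(b) == 0) return(0)
  stats::cor(a, b)^2
}

#' All in-window pairwise r-squared values
#'
#' Computes r-squared for every pair of SNPs on the same chromosome whose
#' positions differ by at most `window_bp`.  Used by [ld_prune()]; exposed
#' so that the (expensive) correlation pass can be shared across several
#' pruning thresholds.
#'
#' @param cohort A [geno_cohort()] whose SNP table is sorted by
#'   `(chrom, pos)`.
#' @param window_bp Window size in base pairs (default 200000).
#' @return A tibble with columns `i`, `j` (SNP column indices, `i < j`)
#'   and `r2`.
#' @export
ld_windowed_r2 <- function(cohort, window_bp = 200000) {
  check_sorted_snps(cohort$snps)
  d <- cohort$dosage
  m <- ncol(d)
  storage.mode(d) <- "double"
  M <- !is.na(d)
  X <- d
  X[!M] <- 0
  X2 <- X * X
  Mn <- matrix(as.double(M), nrow = nrow(d))
  pos <- cohort$snps$pos
  chrom <- cohort$snps$chrom
  out_i <- vector("list", m)
  out_j <- vector("list", m)
  out_r2 <- vector("list", m)
  for (i in seq_len(m)) {
    j_hi <- i
    while (j_hi < m && chrom[j_hi + 1] == chrom[i] &&
           pos[j_hi + 1] - pos[i] <= window_bp) {
      j_hi <- j_hi + 1
    }
    if (j_hi == i) next
    js <- (i + 1):j_hi
    xi <- X[, i]
    mi <- Mn[, i]
    x2i <- X2[, i]
    Aj <- X[, js, drop = FALSE]
    Mj <- Mn[, js, drop = FALSE]
    A2j <- X2[, js, drop = FALSE]
    np <- as.vector(crossprod(mi, Mj))
    sx <- as.vector(crossprod(xi, Mj))
    sy <- as.vector(crossprod(mi, Aj))
    sxx <- as.vector(crossprod(x2i, Mj))
    syy <- as.vector(crossprod(mi, A2j))
    sxy <- as.vector(crossprod(xi, Aj))
    vx <- np * sxx - sx^2
    vy <- np * syy - sy^2
    cv <- np * sxy - sx * sy
    r2 <- ifelse(np >= 2 & vx > 0 & vy > 0, cv^2 / (vx * vy), 0)
    out_i[[i]] <- rep.int(i, length(js))
    out_j[[i]] <- js
    out_r2[[i]] <- r2
  }
  tibble(i = unlist(out_i) %||% integer(), j = unlist(out_j) %||% integer(),
         r2 = unlist(out_r2) %||% numeric())
}

check_sorted_snps <- function(snps) {
  if (is.unsorted(match(snps$chrom, unique(snps$chrom))) ||
      any(diff(snps$pos) < 0 & snps$chrom[-1] == snps$chrom[-nrow(snps)])) {
    abort("SNP table must be sorted by (chrom, pos); not sorting silently")
  }
  invisible(TRUE)
}

#' Greedy windowed LD pruning
#'
#' Produces an "LD-independent" SNP set: a single greedy left-to-right
#' scan per chromosome in which, for each still-retained SNP, every later
#' SNP within `window_bp` whose genotype r-squared with it exceeds
#' `r2_threshold` triggers a removal.  The member of the offending pair
#' with the lower minor-allele frequency is removed; at equal MAF the one
#' at the larger position.  No retained pair within a window exceeds the
#' threshold, and the output preserves input order.
#'
#' @param cohort A [geno_cohort()] sorted by `(chrom, pos)`, QC applied.
#' @param r2_threshold Pairs with r-squared above this are broken up.
#' @param window_bp Window size in base pairs (default 200000).
#' @param maf Optional per-SNP MAF vector for the tie rule (defaults to
#'   the within-cohort MAF over all subjects).
#' @param pairs Optional precomputed [ld_windowed_r2()] table for this
#'   cohort and window, to share across thresholds.
#' @return Character vector of retained `snp_id`s, in input order.
#' @export
ld_prune <- function(cohort, r2_threshold, window_bp = 200000,
                     maf = NULL, pairs = NULL) {
  stopifnot(r2_threshold > 0, r2_threshold < 1, window_bp > 0)
  check_sorted_snps(cohort$snps)
  m <- ncol(cohort$dosage)
  if (is.null(maf)) {
    f1 <- colMeans(cohort$dosage, na.rm = TRUE) / 2
    maf <- pmin(f1, 1 - f1)
  }
  if (length(maf) != m) abort("`maf` must have one value per SNP")
  if (is.null(pairs)) pairs <- ld_windowed_r2(cohort, window_bp)
  removed <- logical(m)
  hot <- pairs[pairs$r2 > r2_threshold, , drop = FALSE]
  if (nrow(hot)) {
    # pairs are emitted anchor-major (sorted by i then j), matching the scan
    pi_ <- hot$i
    pj <- hot$j
    for (k in seq_along(pi_)) {
      i <- pi_[k]
      j <- pj[k]
      if (removed[i] || removed[j]) next
      if (maf[j] < maf[i]) {
        removed[j] <- TRUE
      } else if (maf[i] < maf[j]) {
        removed[i] <- TRUE
      } else {
        removed[j] <- TRUE  # equal MAF: drop the larger position
      }
    }
  }
  cohort$snps$snp_id[!removed]
}

#' Write a kept-SNP list
#'
#' One `snp_id` per line, compatible with variant-extract list
#' conventions.
#'
#' @param snp_ids Character vector of SNP ids.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snp_list <- function(snp_ids, path) {
  writeLines(snp_ids, path)
  invisible(path)
}
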