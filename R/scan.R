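## PCA-based SNP outlier scan -------------------------------------------------

#' Principal-component Mahalanobis outlier scan
#'
#' Latent-factor genome scan for SNPs excessively related to population
#' structure: genotypes are mean-imputed and standardized, the top
#' principal components of the individuals are computed, the number of
#' retained components K is chosen by the largest eigenvalue gap among the
#' first `K_init` candidates, each SNP is summarized by its vector of
#' regression z-scores on the K components, and a robust (minimum
#' covariance determinant) Mahalanobis distance of these z-vectors is
#' referred to a chi-squared(K) distribution after genomic-inflation
#' rescaling (distances divided by their median over the chi-squared
#' median).  SNPs are flagged at a Bonferroni-adjusted `alpha` (or
#' Benjamini-Hochberg with `correction = "BH"`).
#'
#' @param dataset a [snp_dataset()] (typically thinned to one SNP per
#'   locus).
#' @param K_init number of candidate components (default 10).
#' @param alpha significance level (default 0.01).
#' @param correction `"bonferroni"` (family-wise, default) or `"BH"`.
#' @return object of class `outlier_scan`: `K`, squared distances `d2`,
#'   inflation factor `gif`, `pvalues`, `threshold`, logical `outliers`
#'   per SNP, `locus` ids, and indices of dropped constant SNPs.
#' @export
pc_outlier_scan <- function(dataset, K_init = 10, alpha = 0.01,
                            correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  stopifnot(K_init >= 1)
  G <- t(dataset$geno)  # individuals x SNPs
  n <- nrow(G)
  if (K_init >= n) stop("K_init must be smaller than the number of individuals")
  ## mean-impute missing calls, drop SNPs constant after imputation
  cm <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G))
  if (length(idx)) G[idx] <- cm[(idx - 1) %/% n + 1]
  sds <- apply(G, 2, sd)
  dropped <- which(sds == 0 | !is.finite(sds))
  keep <- setdiff(seq_len(ncol(G)), dropped)
  if (!length(keep)) stop("all SNP columns are constant")
  Gs <- scale(G[, keep, drop = FALSE])
  sv <- svd(Gs, nu = min(n - 1, K_init + 1), nv = 0)
  lambda <- sv$d^2
  ncand <- min(K_init, length(lambda) - 1)
  gaps <- lambda[seq_len(ncand)] - lambda[seq_len(ncand) + 1]
  K <- which.max(gaps)
  U <- sv$u[, seq_len(K), drop = FALSE]
  ## regression of each standardized SNP on the orthonormal PCs
  B <- crossprod(U, Gs)                         # K x p coefficients
  rss <- pmax(colSums(Gs^2) - colSums(B^2), 0)
  dfree <- max(n - K - 1, 1)
  sigma <- sqrt(pmax(rss / dfree, 1e-12))
  Z <- t(B / rep(sigma, each = K))              # p x K z-scores
  if (K == 1) {
    ctr <- median(Z[, 1])
    sc <- mad(Z[, 1])
    if (sc == 0) sc <- sd(Z[, 1])
    d2 <- ((Z[, 1] - ctr) / sc)^2
  } else {
    ## reweighted MCD: the raw minimum-covariance-determinant estimate is
    ## noisy in higher dimensions, so refit a classical covariance on the
    ## points inside its 97.5% ellipsoid, corrected for the truncation
    rob <- MASS::cov.rob(Z, method = "mcd")
    d2_raw <- stats::mahalanobis(Z, rob$center, rob$cov)
    inl <- d2_raw <= qchisq(0.975, df = K)
    if (sum(inl) > 5 * K) {
      ctr <- colMeans(Z[inl, , drop = FALSE])
      cv <- stats::cov(Z[inl, , drop = FALSE]) /
        (pchisq(qchisq(0.975, K), df = K + 2) / 0.975)
      d2 <- stats::mahalanobis(Z, ctr, cv)
    } else {
      d2 <- d2_raw
    }
  }
  ## the K z-scores of a SNP share one residual-variance estimate with few
  ## degrees of freedom, so their squared Mahalanobis distance is
  ## Hotelling-F distributed, not chi-squared; map distances through the
  ## F -> chi-squared quantile transform (log scale for extreme SNPs)
  ## before the genomic-inflation rescaling
  df2 <- max(dfree - K + 1, 1)
  logp <- pf(d2 * df2 / (K * dfree), df1 = K, df2 = df2,
             lower.tail = FALSE, log.p = TRUE)
  d2 <- qchisq(logp, df = K, lower.tail = FALSE, log.p = TRUE)
  gif <- median(d2) / qchisq(0.5, df = K)
  pv <- pchisq(d2 / gif, df = K, lower.tail = FALSE)
  p_all <- rep(NA_real_, ncol(G))
  p_all[keep] <- pv
  flags <- rep(FALSE, ncol(G))
  if (correction == "bonferroni") {
    threshold <- alpha / length(pv)
    flags[keep] <- pv < threshold
  } else {
    threshold <- alpha
    flags[keep] <- p.adjust(pv, "BH") < alpha
  }
  d2_all <- rep(NA_real_, ncol(G))
  d2_all[keep] <- d2
  structure(list(K = K, K_init = K_init, eigenvalues = lambda,
                 d2 = d2_all, gif = gif, pvalues = p_all, alpha = alpha,
                 correction = correction, threshold = threshold,
                 outliers = flags, locus = dataset$locus,
                 dropped = dropped),
            class = "outlier_scan")
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf("PC outlier scan: K = %d (of %d candidates), GIF = %.2f\n",
              x$K, x$K_init, x$gif))
  cat(sprintf("  %d / %d SNPs flagged (%s, alpha = %g)\n",
              sum(x$outliers), length(x$outliers), x$correction, x$alpha))
  invisible(x)
}

#' Remove outlier loci from a dataset
#'
#' Drops every locus carrying a flagged SNP, producing a neutral dataset
#' for demographic inference.
#'
#' @param dataset the [snp_dataset()] the scan was computed on.
#' @param scan a [pc_outlier_scan()] result.
#' @return filtered [snp_dataset()].
#' @export
remove_outliers <- function(dataset, scan) {
  if (length(scan$outliers) != nrow(dataset$geno))
    stop("scan does not match dataset")
  bad_loci <- unique(scan$locus[scan$outliers])
  ds <- subset_sites(dataset, !(dataset$locus %in% bad_loci))
  ds$loci <- ds$loci[!(ds$loci$locus_id %in% bad_loci), , drop = FALSE]
  rownames(ds$loci) <- NULL
  ds
}

#' Joint Ka/Ks and F_ST candidate screen
#'
#' Joins per-transcript Ka/Ks ratios with per-locus Weir--Cockerham F_ST
#' through a RAD-locus-to-transcript mapping and flags candidates under
#' positive selection with high differentiation
#' (`ratio > ka_ks_min & fst > fst_min`).  Mapping rows referencing
#' unknown loci or transcripts are skipped with a warning.
#'
#' @param kaks_table data.frame with `transcript_id` and `ratio` (e.g.
#'   built from [ng86_kaks()] results).
#' @param fst_per_locus data.frame with `locus_id` and `fst` (e.g.
#'   `weir_cockerham_fst(ds)$per_locus`).
#' @param mapping data.frame with `locus_id`, `transcript_id`.
#' @param ka_ks_min,fst_min screen thresholds (defaults 1.0 and 0.85).
#' @return data.frame of mapped loci ordered by descending F_ST then
#'   ratio, with a logical `pass` column.
#' @export
candidate_screen <- function(kaks_table, fst_per_locus, mapping,
                             ka_ks_min = 1.0, fst_min = 0.85) {
  unknown_l <- !(mapping$locus_id %in% fst_per_locus$locus_id)
  unknown_t <- !(mapping$transcript_id %in% kaks_table$transcript_id)
  if (any(unknown_l | unknown_t))
    warning(sum(unknown_l | unknown_t),
            " mapping row(s) reference unknown ids; skipped")
  m <- mapping[!(unknown_l | unknown_t), , drop = FALSE]
  out <- data.frame(
    locus_id = m$locus_id,
    transcript_id = m$transcript_id,
    ratio = kaks_table$ratio[match(m$transcript_id, kaks_table$transcript_id)],
    fst = fst_per_locus$fst[match(m$locus_id, fst_per_locus$locus_id)]
  )
  out$pass <- !is.na(out$ratio) & !is.na(out$fst) &
    out$ratio > ka_ks_min & out$fst > fst_min
  out[order(-out$fst, -out$ratio, out$locus_id), , drop = FALSE]
}
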