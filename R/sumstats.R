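## Two-population summary statistics ------------------------------------------

## per-site allele tallies from a dosage matrix (sites x individuals)
site_counts <- function(geno) {
  called <- !is.na(geno)
  list(
    alt = rowSums(geno, na.rm = TRUE),            # alt allele count
    n   = 2L * rowSums(called),                   # called alleles
    het = rowSums(geno == 1L, na.rm = TRUE),      # heterozygotes
    nind = rowSums(called)                        # called individuals
  )
}

#' Tajima's D
#'
#' Computed from the non-missing allele calls at each site.  The per-site
#' nucleotide diversity uses the per-site called-allele count; the constants
#' a1, e1, e2 use a single sample size `n` -- by default the modal per-site
#' called-allele count across segregating sites (set
#' `n_convention = "per_site_min"` to use the minimum instead).
#'
#' @param geno dosage matrix (sites x individuals) for one population, or a
#'   binary haplotype matrix with `ploidy = 1`.
#' @param ploidy 2 for genotype dosage input, 1 for haplotypes.
#' @param n_convention how to pick the sample size for the normalizing
#'   constants.
#' @return Tajima's D, or `NA_real_` when there are no segregating sites.
#' @export
tajimas_d <- function(geno, ploidy = 2, n_convention = c("modal", "per_site_min")) {
  n_convention <- match.arg(n_convention)
  geno <- as.matrix(geno)
  if (ncol(geno) * ploidy < 2) stop("need at least 2 sequences")
  called <- !is.na(geno)
  alt <- rowSums(geno, na.rm = TRUE)
  n_s <- ploidy * rowSums(called)
  seg <- alt > 0 & alt < n_s & n_s >= 2
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  alt <- alt[seg]; n_s <- n_s[seg]
  pi_sites <- 2 * alt * (n_s - alt) / (n_s * (n_s - 1))
  pi <- sum(pi_sites)
  n <- if (n_convention == "modal") {
    tab <- table(n_s)
    as.integer(names(tab)[which.max(tab)])
  } else min(n_s)
  if (n < 4) stop("need at least 4 sequences with data to normalize D")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Hudson's F_ST pooled across loci
#'
#' `1 - Hw/Hb`: mean within-population diversity over mean
#' between-population diversity, summed over sites before taking the
#' ratio, with the frequency-plugin form `Hw = 2p(1-p)` (sequence pairs
#' drawn with replacement), so equal allele frequencies give exactly 0 and
#' all-fixed differences exactly 1.  Only sites with at least 2 called
#' alleles in each population contribute.
#'
#' @param dataset a [snp_dataset()].
#' @return F_ST estimate (slightly negative values possible), `NA_real_` if
#'   no site has between-population diversity.
#' @export
hudson_fst <- function(dataset) {
  s1 <- site_counts(pop_geno(dataset, 1))
  s2 <- site_counts(pop_geno(dataset, 2))
  use <- s1$n >= 2 & s2$n >= 2
  if (!any(use)) return(NA_real_)
  p1 <- s1$alt[use] / s1$n[use]
  p2 <- s2$alt[use] / s2$n[use]
  hw1 <- 2 * p1 * (1 - p1)
  hw2 <- 2 * p2 * (1 - p2)
  hb <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(hb) == 0) return(NA_real_)
  1 - sum((hw1 + hw2) / 2) / sum(hb)
}

## Weir & Cockerham (1984) variance components for one biallelic site,
## two populations, diploid data with per-population called sizes
wc_components <- function(alt1, n1ind, het1, alt2, n2ind, het2) {
  r <- 2
  n_i <- c(n1ind, n2ind)
  if (any(n_i < 1)) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  p_i <- c(alt1 / (2 * n1ind), alt2 / (2 * n2ind))
  h_i <- c(het1 / n1ind, het2 / n2ind)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc <= 0) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir--Cockerham F_ST
#'
#' The 1984 variance-components estimator (theta-hat), as used by VCFtools:
#' components are summed over the sites of a locus for the per-locus value,
#' and over all sites for the overall mean.  Negative estimates are
#' reported, not clamped; a locus monomorphic across both populations is
#' `NA`.
#'
#' @param dataset a [snp_dataset()].
#' @param per_locus if `TRUE` (default) return per-locus values as well.
#' @return list with `mean` and (optionally) `per_locus`
#'   (data.frame `locus_id`, `fst`, `n_sites`).
#' @export
weir_cockerham_fst <- function(dataset, per_locus = TRUE) {
  s1 <- site_counts(pop_geno(dataset, 1))
  s2 <- site_counts(pop_geno(dataset, 2))
  comp <- t(vapply(seq_along(s1$alt), function(i) {
    wc_components(s1$alt[i], s1$nind[i], s1$het[i],
                  s2$alt[i], s2$nind[i], s2$het[i])
  }, numeric(3)))
  tot <- comp[, 1] + comp[, 2] + comp[, 3]
  ok <- !is.na(tot)
  mean_fst <- if (any(ok) && sum(tot[ok]) != 0)
    sum(comp[ok, 1]) / sum(tot[ok]) else NA_real_
  out <- list(mean = mean_fst)
  if (per_locus) {
    f <- factor(dataset$locus, levels = unique(dataset$locus))
    per <- vapply(split(seq_along(f), f), function(i) {
      i <- i[ok[i]]
      if (!length(i) || sum(tot[i]) == 0) return(NA_real_)
      sum(comp[i, 1]) / sum(tot[i])
    }, numeric(1))
    out$per_locus <- data.frame(locus_id = levels(f), fst = unname(per),
                                n_sites = as.integer(table(f)))
  }
  out
}

#' Classify SNPs as shared, fixed, or private polymorphisms
#'
#' On SNPs where both population samples have data and the pooled sample is
#' polymorphic: \emph{shared} = polymorphic in both samples, \emph{fixed} =
#' alternative alleles fixed between the samples, \emph{private_i} =
#' polymorphic only in population i.  The four proportions sum to 1.
#'
#' @param dataset a [snp_dataset()].
#' @return named numeric: `prop_shared`, `prop_fixed`, `prop_private1`,
#'   `prop_private2`, with attribute `n_snps`.
#' @export
allele_sharing <- function(dataset) {
  s1 <- site_counts(pop_geno(dataset, 1))
  s2 <- site_counts(pop_geno(dataset, 2))
  use <- s1$n >= 1 & s2$n >= 1 &
    (s1$alt + s2$alt) > 0 & (s1$alt + s2$alt) < (s1$n + s2$n)
  if (!any(use)) stop("dataset has no polymorphic site with data in both populations")
  poly1 <- s1$alt[use] > 0 & s1$alt[use] < s1$n[use]
  poly2 <- s2$alt[use] > 0 & s2$alt[use] < s2$n[use]
  p1 <- s1$alt[use] / s1$n[use]
  p2 <- s2$alt[use] / s2$n[use]
  fixed <- (p1 == 0 & p2 == 1) | (p1 == 1 & p2 == 0)
  shared <- poly1 & poly2
  priv1 <- poly1 & !poly2
  priv2 <- poly2 & !poly1
  n <- sum(use)
  out <- c(prop_shared = sum(shared) / n, prop_fixed = sum(fixed) / n,
           prop_private1 = sum(priv1) / n, prop_private2 = sum(priv2) / n)
  attr(out, "n_snps") <- n
  out
}

#' Per-population diversity indices and differentiation report
#'
#' Observed heterozygosity (HO), unbiased expected heterozygosity
#' (HE = 2p(1-p) n/(n-1) on the n called alleles), the inbreeding
#' coefficient F_IS = 1 - HO/HE (over sites polymorphic within the
#' population; monomorphic sites have HE = 0 and are excluded), private
#' allele counts, and Weir--Cockerham F_ST per locus and overall.
#'
#' @param dataset a [snp_dataset()].
#' @return object of class `diversity_report`.
#' @export
diversity_report <- function(dataset) {
  per_pop <- lapply(1:2, function(k) {
    g <- pop_geno(dataset, k)
    s <- site_counts(g)
    poly <- s$n >= 2 & s$alt > 0 & s$alt < s$n
    if (!any(poly))
      return(list(HO = NA_real_, HE = NA_real_, FIS = NA_real_))
    p <- s$alt[poly] / s$n[poly]
    he <- 2 * p * (1 - p) * s$n[poly] / (s$n[poly] - 1)
    ho <- s$het[poly] / s$nind[poly]
    list(HO = mean(ho), HE = mean(he), FIS = 1 - mean(ho) / mean(he))
  })
  s1 <- site_counts(pop_geno(dataset, 1))
  s2 <- site_counts(pop_geno(dataset, 2))
  both <- s1$n >= 1 & s2$n >= 1
  has_ref <- function(s) s$alt < s$n
  has_alt <- function(s) s$alt > 0
  ## alleles present in one sample and absent from the other
  priv1 <- sum((has_alt(s1) & !has_alt(s2) & both)) +
    sum((has_ref(s1) & !has_ref(s2) & both))
  priv2 <- sum((has_alt(s2) & !has_alt(s1) & both)) +
    sum((has_ref(s2) & !has_ref(s1) & both))
  wc <- weir_cockerham_fst(dataset, per_locus = TRUE)
  structure(list(
    pop_labels = levels(dataset$pop),
    HO = c(per_pop[[1]]$HO, per_pop[[2]]$HO),
    HE = c(per_pop[[1]]$HE, per_pop[[2]]$HE),
    FIS = c(per_pop[[1]]$FIS, per_pop[[2]]$FIS),
    private_alleles = c(priv1, priv2),
    fst_per_locus = wc$per_locus,
    mean_fst = wc$mean
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat("Diversity report (Weir-Cockerham F_ST)\n")
  for (k in 1:2)
    cat(sprintf("  %s: HO = %.4f  HE = %.4f  F_IS = %.4f  private alleles = %d\n",
                x$pop_labels[k], x$HO[k], x$HE[k], x$FIS[k], x$private_alleles[k]))
  cat(sprintf("  mean F_ST = %.4f over %d loci\n", x$mean_fst,
              nrow(x$fst_per_locus)))
  invisible(x)
}

#' Joint site frequency spectrum
#'
#' Counts SNPs by alternative-allele count in population 1 x population 2.
#' Sites with missing calls are either dropped (`missing = "drop"`, keeps
#' only complete-data sites) or projected down to `project` called alleles
#' per population by the expected hypergeometric subsample
#' (`missing = "project"`, fractional counts).
#'
#' @param dataset a [snp_dataset()].
#' @param folded fold to the minor-allele spectrum.
#' @param missing `"drop"` or `"project"`.
#' @param project integer vector of 2: target called-allele counts per
#'   population when projecting.
#' @return object of class `joint_sfs`: a counts `matrix` with row index =
#'   pop1 allele count 0..n1 and a `folded` flag.
#' @export
joint_sfs <- function(dataset, folded = FALSE, missing = c("drop", "project"),
                      project = NULL) {
  missing <- match.arg(missing)
  s1 <- site_counts(pop_geno(dataset, 1))
  s2 <- site_counts(pop_geno(dataset, 2))
  n1 <- 2L * n_pop(dataset, 1); n2 <- 2L * n_pop(dataset, 2)
  if (missing == "drop") {
    use <- s1$n == n1 & s2$n == n2
    M <- matrix(0, n1 + 1, n2 + 1)
    if (any(use)) {
      tab <- table(factor(s1$alt[use], levels = 0:n1),
                   factor(s2$alt[use], levels = 0:n2))
      M <- M + unclass(tab)
    }
  } else {
    if (is.null(project)) project <- c(n1, n2)
    m1 <- project[1]; m2 <- project[2]
    use <- s1$n >= m1 & s2$n >= m2
    M <- matrix(0, m1 + 1, m2 + 1)
    for (i in which(use)) {
      w1 <- dhyper(0:m1, s1$alt[i], s1$n[i] - s1$alt[i], m1)
      w2 <- dhyper(0:m2, s2$alt[i], s2$n[i] - s2$alt[i], m2)
      M <- M + outer(w1, w2)
    }
  }
  dimnames(M) <- list(pop1 = 0:(nrow(M) - 1), pop2 = 0:(ncol(M) - 1))
  if (folded) M <- fold_jsfs(M)
  structure(list(counts = M, folded = folded), class = "joint_sfs")
}

## fold a joint SFS: add each cell to its point reflection, keep the
## low-total-frequency half, halve nothing (self-complementary cell keeps
## its own count once)
fold_jsfs <- function(M) {
  n1 <- nrow(M) - 1; n2 <- ncol(M) - 1
  Rm <- M[n1:0 + 1, n2:0 + 1, drop = FALSE]  # point reflection
  Fm <- M + Rm
  keep <- matrix(FALSE, n1 + 1, n2 + 1)
  for (i in 0:n1) for (j in 0:n2) {
    tot <- i + j
    if (tot * 2 < n1 + n2) keep[i + 1, j + 1] <- TRUE
    else if (tot * 2 == n1 + n2) {
      ri <- n1 - i; rj <- n2 - j
      if (i == ri && j == rj) {
        keep[i + 1, j + 1] <- TRUE
        Fm[i + 1, j + 1] <- M[i + 1, j + 1]  # self-complementary: count once
      } else if (i < ri || (i == ri && j < rj)) {
        keep[i + 1, j + 1] <- TRUE  # tie-break: keep the lower pop1 count
      }
    }
  }
  Fm[!keep] <- 0
  dimnames(Fm) <- dimnames(M)
  Fm
}

#' The five ABC summary statistics
#'
#' Assembles, in fixed order: Tajima's D in population 1 and population 2,
#' Hudson's F_ST, and the proportions of shared and fixed SNPs.  Undefined
#' components propagate as `NA` and the vector is flagged via the
#' `"flagged"` attribute.
#'
#' @param dataset a [snp_dataset()], already thinned/filtered as configured.
#' @return named numeric of length 5 with attribute `flagged`.
#' @export
summary_vector <- function(dataset) {
  d1 <- tryCatch(tajimas_d(pop_geno(dataset, 1)), error = function(e) NA_real_)
  d2 <- tryCatch(tajimas_d(pop_geno(dataset, 2)), error = function(e) NA_real_)
  fst <- hudson_fst(dataset)
  sh <- tryCatch(allele_sharing(dataset),
                 error = function(e) c(prop_shared = NA_real_, prop_fixed = NA_real_))
  out <- c(tajd_pop1 = d1, tajd_pop2 = d2, fst = fst,
           prop_shared = unname(sh["prop_shared"]),
           prop_fixed = unname(sh["prop_fixed"]))
  attr(out, "flagged") <- anyNA(out)
  out
}

STAT_NAMES <- c("tajd_pop1", "tajd_pop2", "fst", "prop_shared", "prop_fixed")
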