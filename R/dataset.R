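## SNP dataset container ------------------------------------------------------

#' Construct a two-population SNP dataset
#'
#' The unit every statistic consumes: per-locus biallelic diploid genotypes
#' for two population samples, coded as alternative-allele dosage
#' (0/1/2, `NA` = missing call).
#'
#' @param geno integer matrix, sites x individuals, values in
#'   `{0, 1, 2, NA}`.
#' @param locus character vector, locus id per site.
#' @param position numeric vector, within-locus coordinate per site.
#' @param loci data.frame with `locus_id`, `length_bp`, `n_sites` (may list
#'   monomorphic loci with `n_sites = 0`).
#' @param pop character/factor per individual, two levels; the first level
#'   is "population 1" throughout the package.
#' @param provenance `"simulated"` or `"file"`.
#' @return object of class `snp_dataset`.
#' @export
snp_dataset <- function(geno, locus, position = rep(NA_real_, nrow(geno)),
                        loci = NULL, pop, provenance = "file") {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(locus))
    stop("one locus id required per site")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  pop <- as.factor(pop)
  if (nlevels(pop) != 2) stop("exactly two populations required")
  if (length(pop) != ncol(geno))
    stop("one population label required per individual")
  if (is.null(loci)) {
    tab <- table(factor(locus, levels = unique(locus)))
    loci <- data.frame(locus_id = names(tab), length_bp = NA_integer_,
                       n_sites = as.integer(tab))
  }
  structure(list(geno = geno, locus = as.character(locus),
                 position = position, loci = loci, pop = pop,
                 provenance = provenance),
            class = "snp_dataset")
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat(sprintf("snp_dataset: %d SNPs on %d loci (%d monomorphic), %d + %d individuals [%s]\n",
              nrow(x$geno), nrow(x$loci), sum(x$loci$n_sites == 0),
              sum(x$pop == levels(x$pop)[1]), sum(x$pop == levels(x$pop)[2]),
              x$provenance))
  miss <- if (length(x$geno)) mean(is.na(x$geno)) else 0
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

n_pop <- function(dataset, which_pop) {
  sum(dataset$pop == levels(dataset$pop)[which_pop])
}

pop_geno <- function(dataset, which_pop) {
  dataset$geno[, dataset$pop == levels(dataset$pop)[which_pop], drop = FALSE]
}

subset_sites <- function(dataset, keep) {
  dataset$geno <- dataset$geno[keep, , drop = FALSE]
  dataset$locus <- dataset$locus[keep]
  dataset$position <- dataset$position[keep]
  counts <- table(factor(dataset$locus, levels = dataset$loci$locus_id))
  dataset$loci$n_sites <- as.integer(counts)
  dataset
}

#' Keep one random SNP per locus
#'
#' Emulates the standard RAD-seq thinning to unlinked markers: for every
#' locus with at least one SNP, one site is retained uniformly at random
#' (deterministic under `set.seed()`); loci without SNPs are dropped from
#' the SNP table (but remain listed in `loci`).
#'
#' @param dataset a [snp_dataset()].
#' @return thinned [snp_dataset()].
#' @export
one_random_snp_per_locus <- function(dataset) {
  idx <- split(seq_along(dataset$locus),
               factor(dataset$locus, levels = unique(dataset$locus)))
  pick <- vapply(idx, function(i) if (length(i) == 1L) i else
    i[sample.int(length(i), 1L)], integer(1))
  subset_sites(dataset, sort(pick))
}

#' Filter loci by missing-data fraction
#'
#' Removes loci whose fraction of missing genotype calls (over the locus's
#' SNP rows and all individuals) exceeds `max_missing_fraction`.  A
#' threshold of 0 keeps only loci with complete data.
#'
#' @param dataset a [snp_dataset()].
#' @param max_missing_fraction maximum tolerated missing fraction in
#'   `[0, 1]`.
#' @return filtered [snp_dataset()] (the `loci` table is subset too).
#' @export
filter_missing <- function(dataset, max_missing_fraction) {
  if (max_missing_fraction < 0 || max_missing_fraction > 1)
    stop("max_missing_fraction must lie in [0, 1]")
  if (!nrow(dataset$geno)) return(dataset)
  fr <- vapply(split(seq_along(dataset$locus), dataset$locus),
               function(i) mean(is.na(dataset$geno[i, , drop = FALSE])),
               numeric(1))
  bad_loci <- names(fr)[fr > max_missing_fraction]
  dataset <- subset_sites(dataset, !(dataset$locus %in% bad_loci))
  dataset$loci <- dataset$loci[!(dataset$loci$locus_id %in% bad_loci), ,
                               drop = FALSE]
  rownames(dataset$loci) <- NULL
  dataset
}
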