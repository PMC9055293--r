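## Locus simulation -----------------------------------------------------------

#' Describe loci to simulate
#'
#' @param n_loci number of loci.
#' @param length_bp locus length in base pairs (recycled).
#' @param mu mutation rate per site per generation (recycled).
#' @param n1,n2 haploid sample sizes per deme.
#' @return list of locus specifications (`length_bp`, `mu`, `n1`, `n2`).
#' @export
make_loci <- function(n_loci, length_bp = 500, mu = 1e-9, n1 = 24, n2 = 24) {
  length_bp <- rep_len(length_bp, n_loci)
  mu <- rep_len(mu, n_loci)
  lapply(seq_len(n_loci), function(i) {
    locus_spec(length_bp[i], mu[i], n1, n2)
  })
}

locus_spec <- function(length_bp, mu, n1, n2) {
  if (length_bp < 1) stop("length_bp must be >= 1")
  if (mu <= 0) stop("mu must be > 0")
  if (n1 + n2 < 1) stop("need at least one sampled haplotype")
  list(length_bp = as.integer(length_bp), mu = mu,
       n1 = as.integer(n1), n2 = as.integer(n2))
}

## scenario -> scaled epoch matrix for the C++ core
## columns: t0, t1 (units of 4*N0 generations), bw12, bw21 (backward jump
## rates; bw12 moves a pop1 lineage to pop2 = forward-time flow 2 -> 1)
scaled_epochs <- function(scenario) {
  ep <- scenario$epochs
  s <- function(t) years_to_coalescent(t, scenario$N0, scenario$gen_time)
  cbind(t0 = s(ep$t_start), t1 = s(ep$t_end),
        bw12 = ep$rate_2to1, bw21 = ep$rate_1to2)
}

#' Simulate one locus under a divergence scenario
#'
#' Hudson-style structured coalescent with infinite-sites mutation and no
#' recombination.  Time is in units of 4*N0 generations; demes coalesce at
#' rate k(k-1)/2 scaled by N0/NE_i, lineages migrate backwards at the
#' scenario's scaled rates, the demes merge into the ancestral population
#' (size N0) at the divergence time, and mutations fall on branches as a
#' Poisson process with per-locus theta = 4*N0*mu*length_bp.
#'
#' Randomness comes from R's RNG: call `set.seed()` for reproducibility.
#'
#' @param scenario a [build_scenario()] object.
#' @param locus a single element of [make_loci()].
#' @return object of class `haplotype_matrix`: binary `alleles` matrix
#'   (segregating sites x haplotypes), `positions` in `[0, 1)` sorted
#'   increasing, and `deme_of_sample`.
#' @export
simulate_locus <- function(scenario, locus) {
  stopifnot(inherits(scenario, "dem_scenario"))
  theta <- 4 * scenario$N0 * locus$mu * locus$length_bp
  res <- .sim_locus_cpp(
    locus$n1, locus$n2,
    scenario$NE1 / scenario$N0, scenario$NE2 / scenario$N0,
    years_to_coalescent(scenario$T_div, scenario$N0, scenario$gen_time),
    scaled_epochs(scenario), theta
  )
  haps <- res$haps
  pos <- res$positions
  ## infinite sites on a finite alphabet of branches can still produce
  ## duplicated tip patterns; sites are kept as-is (each mutation is a site)
  ord <- order(pos)
  haps <- haps[ord, , drop = FALSE]
  pos <- pos[ord]
  structure(list(
    alleles = haps, positions = pos,
    deme_of_sample = rep(1:2, c(locus$n1, locus$n2))
  ), class = "haplotype_matrix")
}

#' Simulate a diploid SNP dataset under a scenario
#'
#' Wraps [simulate_locus()] over a set of loci and emulates the features of
#' a real RAD-seq genotype table: haplotypes are paired into diploids within
#' demes; with probability `inbreeding_f[pop]` an individual's second
#' haplotype at a locus duplicates its first (an excess-homozygosity model
#' whose expected F_IS equals the coefficient); genotype calls are masked
#' missing independently at `missing_rate`.  Loci with no segregating sites
#' are recorded as monomorphic (zero SNP rows, still listed in `loci`).
#'
#' @param scenario a [build_scenario()] object.
#' @param loci list from [make_loci()]; haploid sizes must be even.
#' @param inbreeding_f per-deme inbreeding coefficients in `[0, 1]`.
#' @param missing_rate per-call missing probability in `[0, 1)`.
#' @return a [snp_dataset()].
#' @export
simulate_dataset <- function(scenario, loci, inbreeding_f = c(0, 0),
                             missing_rate = 0) {
  inbreeding_f <- rep_len(inbreeding_f, 2)
  if (any(inbreeding_f < 0) || any(inbreeding_f > 1))
    stop("inbreeding_f must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  n1 <- loci[[1]]$n1; n2 <- loci[[1]]$n2
  if (n1 %% 2 != 0 || n2 %% 2 != 0)
    stop("haploid sample sizes must be even to pair into diploids")
  d1 <- n1 %/% 2; d2 <- n2 %/% 2
  nind <- d1 + d2
  f_ind <- rep(inbreeding_f, c(d1, d2))
  first_hap <- c(seq(1, n1, by = 2), n1 + seq(1, n2, by = 2))

  geno_list <- vector("list", length(loci))
  locus_ids <- sprintf("locus%d", seq_along(loci))
  pos_list <- vector("list", length(loci))
  n_sites <- integer(length(loci))
  for (j in seq_along(loci)) {
    hm <- simulate_locus(scenario, loci[[j]])
    s <- nrow(hm$alleles)
    n_sites[j] <- s
    if (s == 0L) next
    a <- hm$alleles
    ## diploid pairing; inbred individuals duplicate their first haplotype
    inbred <- runif(nind) < f_ind
    g <- a[, first_hap, drop = FALSE] + a[, first_hap + 1L, drop = FALSE]
    if (any(inbred))
      g[, inbred] <- 2L * a[, first_hap[inbred], drop = FALSE]
    if (missing_rate > 0)
      g[matrix(runif(length(g)) < missing_rate, nrow = s)] <- NA_integer_
    geno_list[[j]] <- g
    pos_list[[j]] <- hm$positions
  }
  keep <- n_sites > 0L
  geno <- if (any(keep)) do.call(rbind, geno_list[keep]) else
    matrix(integer(0), 0, nind)
  snp_dataset(
    geno = geno,
    locus = rep(locus_ids[keep], n_sites[keep]),
    position = unlist(pos_list[keep]) %||% numeric(0),
    loci = data.frame(locus_id = locus_ids,
                      length_bp = vapply(loci, `[[`, integer(1), "length_bp"),
                      n_sites = n_sites),
    pop = rep(c("pop1", "pop2"), c(d1, d2)),
    provenance = "simulated"
  )
}

#' Write haplotype matrices in ms-style text
#'
#' One `//` block per locus with `segsites:` and `positions:` lines, for
#' interoperability and eyeball debugging.
#'
#' @param sims list of `haplotype_matrix` objects.
#' @param path output file.
#' @export
write_ms <- function(sims, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- ncol(sims[[1]]$alleles)
  writeLines(c(sprintf("divabc %d %d", n, length(sims)), ""), con)
  for (hm in sims) {
    writeLines("//", con)
    writeLines(sprintf("segsites: %d", nrow(hm$alleles)), con)
    if (nrow(hm$alleles) > 0) {
      writeLines(paste("positions:",
                       paste(sprintf("%.5f", hm$positions), collapse = " ")), con)
      writeLines(apply(hm$alleles, 2, paste, collapse = ""), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
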