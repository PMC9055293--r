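# Independent brute-force oracles and fixture builders.  These deliberately
# re-derive every statistic from first principles (pair enumeration, explicit
# path enumeration) so they share no code with the package implementations.

# Tajima's D by direct evaluation of the 1989 formulas on enumerated
# pairwise differences between haplotype columns
oracle_tajima_haps <- function(haps) {
  n <- ncol(haps)
  S <- sum(apply(haps, 1, function(r) length(unique(r)) > 1))
  if (S == 0) return(NA_real_)
  pi_sum <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    pi_sum <- pi_sum + sum(haps[, i] != haps[, j])
  pi <- pi_sum / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# Hudson F_ST by exhaustive enumeration of allele-call pairs: expand each
# individual's dosage into two allele calls, compare all ordered
# with-replacement pairs within populations (the frequency-plugin
# convention) and all cross-population pairs at each site
oracle_hudson <- function(geno1, geno2) {
  hw_num <- hb_num <- 0
  expand <- function(g) {
    g <- g[!is.na(g)]
    unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
  }
  for (s in seq_len(nrow(geno1))) {
    a1 <- expand(geno1[s, ]); a2 <- expand(geno2[s, ])
    if (length(a1) < 2 || length(a2) < 2) next
    hw_site <- 0
    for (al in list(a1, a2)) {
      diffs <- 0; tot <- 0
      for (i in seq_along(al)) for (j in seq_along(al)) {
        diffs <- diffs + (al[i] != al[j]); tot <- tot + 1
      }
      hw_site <- hw_site + diffs / tot
    }
    hw_num <- hw_num + hw_site / 2
    db <- 0; tb <- 0
    for (x in a1) for (y in a2) { db <- db + (x != y); tb <- tb + 1 }
    hb_num <- hb_num + db / tb
  }
  1 - hw_num / hb_num
}

# Weir & Cockerham (1984) theta-hat, written directly from the published
# variance components for two populations
oracle_wc <- function(geno1, geno2) {
  asum <- dsum <- 0
  for (s in seq_len(nrow(geno1))) {
    g1 <- geno1[s, ][!is.na(geno1[s, ])]
    g2 <- geno2[s, ][!is.na(geno2[s, ])]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 1 || n2 < 1) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (ssq - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * ssq - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    asum <- asum + a
    dsum <- dsum + a + b + cc
  }
  asum / dsum
}

# NG86 by explicit recursion over all substitution orderings, using the
# Biostrings genetic code; stop-crossing paths excluded when avoidable
oracle_ng86 <- function(s1, s2) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(s1) / 3
  cods <- function(s) substring(s, 3 * (1:n) - 2, 3 * (1:n))
  c1 <- cods(toupper(s1)); c2 <- cods(toupper(s2))
  syn_sites <- function(cod) {
    aa <- code[[cod]]
    tot <- 0
    for (p in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == substr(cod, p, p)) next
      alt <- cod; substr(alt, p, p) <- b
      if (code[[alt]] == aa && code[[alt]] != "*") tot <- tot + 1 / 3
    }
    tot
  }
  walk <- function(from, to, allow_stop) {
    pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (!length(pos)) return(list(c(0, 0)))
    out <- list()
    for (p in pos) {
      mid <- from; substr(mid, p, p) <- substr(to, p, p)
      if (!allow_stop && code[[mid]] == "*" && mid != to) next
      step_syn <- code[[mid]] != "*" && code[[mid]] == code[[from]]
      for (rest in walk(mid, to, allow_stop))
        out[[length(out) + 1]] <- rest + if (step_syn) c(1, 0) else c(0, 1)
    }
    out
  }
  S <- (sum(vapply(c1, syn_sites, 0)) + sum(vapply(c2, syn_sites, 0))) / 2
  N <- 3 * n - S
  Sd <- Nd <- 0
  for (i in 1:n) {
    paths <- walk(c1[i], c2[i], allow_stop = FALSE)
    if (!length(paths)) paths <- walk(c1[i], c2[i], allow_stop = TRUE)
    avg <- Reduce(`+`, paths) / length(paths)
    Sd <- Sd + avg[1]; Nd <- Nd + avg[2]
  }
  jc <- function(p) if (p == 0) 0 else -3 / 4 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), S = S, N = N, Sd = Sd, Nd = Nd)
}

# dataset fixture from two dosage matrices (sites x individuals)
toy_dataset <- function(geno1, geno2, locus = NULL) {
  geno <- cbind(geno1, geno2)
  if (is.null(locus)) locus <- sprintf("locus%d", seq_len(nrow(geno)))
  snp_dataset(
    geno = geno, locus = locus,
    loci = data.frame(locus_id = unique(locus), length_bp = 500L,
                      n_sites = as.integer(table(factor(locus, levels = unique(locus))))),
    pop = rep(c("pop1", "pop2"), c(ncol(geno1), ncol(geno2))),
    provenance = "file"
  )
}

# genotype matrix (sites x n_ind) with given alt-allele counts split into
# hom-alt and het individuals, for planted-count fixtures
geno_from_counts <- function(n_ind, hom_alt, het) {
  stopifnot(length(hom_alt) == length(het))
  t(vapply(seq_along(hom_alt), function(s) {
    g <- c(rep(2L, hom_alt[s]), rep(1L, het[s]),
           rep(0L, n_ind - hom_alt[s] - het[s]))
    g
  }, integer(n_ind)))
}

# small two-deme simulated dataset used by several tests
quick_sim_dataset <- function(n_loci = 60, model = "I", t_div = 3e6,
                              theta_mu = 1e-8, M = NULL, n_dip = 12,
                              inbreeding = c(0, 0), missing = 0) {
  params <- list(N0 = 1e4, gen_time = 5, mu = theta_mu,
                 NE1 = 1e4, NE2 = 1e4, T_div = t_div)
  if (model == "II") params <- c(params, list(M12_old = M, M21_old = M))
  scen <- build_scenario(model, params)
  loci <- make_loci(n_loci, 500, theta_mu, 2 * n_dip, 2 * n_dip)
  simulate_dataset(scen, loci, inbreeding_f = inbreeding,
                   missing_rate = missing)
}
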