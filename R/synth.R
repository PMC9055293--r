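## Synthetic study generator --------------------------------------------------

#' Configuration for a synthetic two-species RAD-seq study
#'
#' Defaults emulate the statistical structure of a 24-individual RAD-seq
#' SNP table from a pair of recently diverged plant species: 12 diploids
#' per species, 1,755 short loci of 500 bp, one random SNP per locus,
#' missing genotype calls, and within-population inbreeding coefficients of
#' 0.16 and 0.20.  The generating truth is the decreasing-migration
#' scenario with divergence 4.7 Mya, descendant sizes 16,673 and 5,906
#' diploids, and old scaled migration rates about 0.5 dropping to recent
#' rates of order 1e-4 at 0.016 / 0.247 Mya.
#'
#' @param model_id generating scenario (default `"V"`).
#' @param truth named list of scenario parameters (defaults above).
#' @param n_loci number of loci (default 1755).
#' @param length_bp locus length (default 500).
#' @param n_diploids diploids per population (default 12).
#' @param inbreeding_f per-population inbreeding (default `c(0.16, 0.20)`).
#' @param missing_rate per-call missing probability (default 0.10, which
#'   keeps per-locus missingness under the conventional 25\% cap for
#'   almost all loci).
#' @param max_missing per-locus missingness filter applied to the final
#'   table (default 0.25).
#' @return list of class `study_config`.
#' @export
study_config <- function(model_id = "V",
                         truth = NULL,
                         n_loci = 1755, length_bp = 500, n_diploids = 12,
                         inbreeding_f = c(0.16, 0.20), missing_rate = 0.10,
                         max_missing = 0.25) {
  default_truth <- list(
    N0 = 1e4, gen_time = 5, mu = 1e-9,
    NE1 = 16673, NE2 = 5906, T_div = 4.7e6,
    M12_old = 0.47, M21_old = 0.50,
    M12_rec = 4e-4, M21_rec = 1.5e-4,
    T_rec_12 = 0.016e6, T_rec_21 = 0.247e6
  )
  truth <- utils::modifyList(default_truth, truth %||% list())
  structure(list(model_id = model_id, truth = truth, n_loci = n_loci,
                 length_bp = length_bp, n_diploids = n_diploids,
                 inbreeding_f = inbreeding_f, missing_rate = missing_rate,
                 max_missing = max_missing),
            class = "study_config")
}

#' Generate a synthetic study dataset
#'
#' Simulates the configured scenario over `n_loci` loci, pairs haplotypes
#' into diploids with the configured inbreeding and missingness, thins to
#' one random SNP per locus, and applies the per-locus missingness filter,
#' so the output obeys the conventions of a real biallelic one-SNP-per-locus
#' RAD-seq table.  Randomness comes from R's RNG (`set.seed()`).
#'
#' @param config a [study_config()].
#' @return list with `dataset` (a [snp_dataset()]) and `truth` (the
#'   generating parameters and scenario id, for recovery tests).
#' @export
generate_study <- function(config = study_config()) {
  relevant <- intersect(names(config$truth),
                        c("N0", "gen_time", "mu", model_params(config$model_id)))
  scen <- build_scenario(config$model_id, config$truth[relevant])
  loci <- make_loci(config$n_loci, length_bp = config$length_bp,
                    mu = config$truth$mu, n1 = 2 * config$n_diploids,
                    n2 = 2 * config$n_diploids)
  ds <- simulate_dataset(scen, loci, inbreeding_f = config$inbreeding_f,
                         missing_rate = config$missing_rate)
  ds <- one_random_snp_per_locus(ds)
  ds <- filter_missing(ds, config$max_missing)
  list(dataset = ds,
       truth = c(config$truth[relevant], list(model_id = config$model_id)))
}

random_cds <- function(n_codons, code) {
  codons <- names(code)[code != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

#' Generate codon-aligned ortholog pairs with a target Ka/Ks
#'
#' For each pair an ancestral coding sequence is drawn and one copy
#' accumulates point substitutions; proposed changes are accepted with
#' probabilities in the ratio `omega : 1` for nonsynonymous versus
#' synonymous changes (acceptance-rejection on uniform proposals), and
#' changes creating stop codons are always rejected.  Realized
#' Nei--Gojobori ratios therefore track the target omega without a full
#' codon-model simulation.
#'
#' @param n_pairs number of ortholog pairs.
#' @param codons_per_gene codons per sequence (>= 10).
#' @param omega target Ka/Ks per pair, recycled (default
#'   `c(0.2, 1, 5)`).
#' @param subs_per_site expected accepted substitutions per nucleotide
#'   site (default 0.05).
#' @return list with `pairs` (named list of `list(seq1, seq2)`) and
#'   `truth` (data.frame `transcript_id`, `omega`, `n_subs`).
#' @export
generate_cds_pairs <- function(n_pairs, codons_per_gene = 100,
                               omega = c(0.2, 1, 5), subs_per_site = 0.05) {
  stopifnot(codons_per_gene >= 10)
  code <- genetic_code()
  omega <- rep_len(omega, n_pairs)
  pairs <- vector("list", n_pairs)
  ids <- sprintf("transcript%d", seq_len(n_pairs))
  n_subs <- integer(n_pairs)
  len <- 3L * codons_per_gene
  for (i in seq_len(n_pairs)) {
    anc <- random_cds(codons_per_gene, code)
    der <- anc
    target <- rpois(1, subs_per_site * len)
    w <- omega[i]
    p_nonsyn <- if (w >= 1) 1 else w
    p_syn <- if (w >= 1) 1 / w else 1
    accepted <- 0L
    proposals <- 0L
    while (accepted < target && proposals < 200 * (target + 1)) {
      proposals <- proposals + 1L
      pos <- sample.int(len, 1)
      old <- substr(der, pos, pos)
      new <- sample(setdiff(BASES, old), 1)
      cstart <- 3 * ((pos - 1) %/% 3) + 1
      cod_old <- substr(der, cstart, cstart + 2)
      cod_new <- cod_old
      substr(cod_new, ((pos - 1) %% 3) + 1, ((pos - 1) %% 3) + 1) <- new
      if (code[[cod_new]] == "*") next
      syn <- code[[cod_new]] == code[[cod_old]]
      if (runif(1) < (if (syn) p_syn else p_nonsyn)) {
        substr(der, pos, pos) <- new
        accepted <- accepted + 1L
      }
    }
    n_subs[i] <- accepted
    pairs[[i]] <- list(seq1 = anc, seq2 = der)
  }
  names(pairs) <- ids
  list(pairs = pairs,
       truth = data.frame(transcript_id = ids, omega = omega,
                          n_subs = n_subs))
}

#' Generate a RAD-locus-to-transcript mapping table
#'
#' Emulates the hit table of a nucleotide search of RAD tags against a
#' transcriptome: a random fraction of the dataset's loci is assigned one
#' transcript each.
#'
#' @param dataset a [snp_dataset()].
#' @param cds_truth the `truth` table of [generate_cds_pairs()].
#' @param fraction_mapped fraction of loci receiving a hit, in `[0, 1]`.
#' @return data.frame with `locus_id`, `transcript_id`.
#' @export
generate_mapping <- function(dataset, cds_truth, fraction_mapped) {
  if (fraction_mapped < 0 || fraction_mapped > 1)
    stop("fraction_mapped must lie in [0, 1]")
  loci <- dataset$loci$locus_id[dataset$loci$n_sites > 0]
  n_map <- round(fraction_mapped * length(loci))
  if (n_map == 0)
    return(data.frame(locus_id = character(0), transcript_id = character(0)))
  chosen <- sort(sample(seq_along(loci), n_map))
  tid <- sample(cds_truth$transcript_id, n_map,
                replace = n_map > nrow(cds_truth))
  data.frame(locus_id = loci[chosen], transcript_id = tid)
}
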