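## Nei-Gojobori (1986) Ka/Ks --------------------------------------------------

genetic_code <- function() Biostrings::GENETIC_CODE

BASES <- c("A", "C", "G", "T")

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length must be divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

## fraction-of-synonymous-changes site counts for one codon:
## c(S, N) with S + N = 3; changes producing stop codons count as
## nonsynonymous
codon_sites <- function(codon, code) {
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (!is.na(code[alt]) && code[[alt]] != "*" && code[[alt]] == aa)
        s <- s + 1 / 3
    }
  }
  c(S = s, N = 3 - s)
}

## all orderings of k positions (k <= 3)
path_orders <- function(pos) {
  k <- length(pos)
  if (k == 1) return(list(pos))
  if (k == 2) return(list(pos, pos[2:1]))
  list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
       pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
}

## average synonymous/nonsynonymous difference counts between two codons
## over all minimal mutational paths; paths through stop codons are
## excluded when any stop-free path exists
codon_diffs <- function(c1, c2, code) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(Sd = 0, Nd = 0))
  tally <- function(order_, allow_stop) {
    cur <- c1
    sd <- nd <- 0
    for (p in order_) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stop && code[[nxt]] == "*" && nxt != c2) return(NULL)
      if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(Sd = sd, Nd = nd)
  }
  paths <- path_orders(pos)
  res <- lapply(paths, tally, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) res <- lapply(paths, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

#' Nei--Gojobori Ka/Ks for a codon-aligned sequence pair
#'
#' The 1986 counting method: synonymous and nonsynonymous site counts are
#' the fraction-of-synonymous-changes tallies averaged over the two
#' sequences; observed differences in multi-difference codons are averaged
#' over all minimal substitution paths (paths through stop codons excluded
#' where possible); proportions are corrected for multiple hits with the
#' Jukes--Cantor formula.  When Ks = 0 and Ka > 0 the ratio is reported as
#' the conventional ceiling 50.000 with `capped = TRUE`; when both are 0
#' the ratio is undefined (`NA`).
#'
#' @param seq1,seq2 equal-length coding sequences (characters,
#'   `DNAString`s, or anything `as.character` turns into one string),
#'   length divisible by 3, no internal stop codons.  Codons containing
#'   gaps (`-`) or `N` in either sequence are deleted pairwise.
#' @return object of class `kaks_result`: `ka`, `ks`, `ratio`, `capped`,
#'   plus the site (`S`, `N`) and difference (`Sd`, `Nd`) counts.
#' @export
ng86_kaks <- function(seq1, seq2) {
  code <- genetic_code()
  s1 <- as.character(seq1); s2 <- as.character(seq2)
  if (nchar(s1) != nchar(s2)) stop("sequences must be aligned to equal length")
  cod1 <- split_codons(s1); cod2 <- split_codons(s2)
  clean <- !grepl("[^ACGT]", cod1) & !grepl("[^ACGT]", cod2)
  cod1 <- cod1[clean]; cod2 <- cod2[clean]
  if (!length(cod1)) stop("no complete codon left after gap removal")
  ## terminal stop codons are tolerated and dropped; internal stops are not
  nc <- length(cod1)
  if (code[[cod1[nc]]] == "*" && code[[cod2[nc]]] == "*") {
    cod1 <- cod1[-nc]; cod2 <- cod2[-nc]
    if (!length(cod1)) stop("no codon left after removing the stop codon")
  }
  if (any(code[cod1] == "*") || any(code[cod2] == "*"))
    stop("internal stop codon in input")

  sites1 <- rowSums(vapply(cod1, codon_sites, numeric(2), code = code))
  sites2 <- rowSums(vapply(cod2, codon_sites, numeric(2), code = code))
  S <- (sites1["S"] + sites2["S"]) / 2
  N <- (sites1["N"] + sites2["N"]) / 2
  d <- rowSums(vapply(seq_along(cod1), function(i)
    codon_diffs(cod1[i], cod2[i], code), numeric(2)))
  Sd <- d["Sd"]; Nd <- d["Nd"]
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 3 / 4)
      stop(sprintf("Jukes-Cantor correction undefined (p = %.3f >= 0.75)", p))
    -3 / 4 * log(1 - 4 * p / 3)
  }
  ka <- if (N > 0) jc(Nd / N) else 0
  ks <- if (S > 0) jc(Sd / S) else 0
  capped <- FALSE
  ratio <- if (ks > 0) ka / ks
  else if (ka > 0) { capped <- TRUE; 50.0 }
  else NA_real_
  structure(list(ka = unname(ka), ks = unname(ks), ratio = unname(ratio),
                 capped = capped,
                 sites = c(S = unname(S), N = unname(N)),
                 diffs = c(Sd = unname(Sd), Nd = unname(Nd)),
                 n_codons = length(cod1)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %.4f  Ks = %.4f  Ka/Ks = %s%s  (%d codons)\n",
              x$ka, x$ks,
              if (is.na(x$ratio)) "undefined" else sprintf("%.3f", x$ratio),
              if (x$capped) " [capped]" else "", x$n_codons))
  invisible(x)
}

#' Tabulate Ka/Ks over many ortholog pairs
#'
#' @param pairs named list of `list(seq1, seq2)` ortholog pairs.
#' @return data.frame with `transcript_id`, `ka`, `ks`, `ratio`, `capped`.
#' @export
kaks_table <- function(pairs) {
  rows <- lapply(names(pairs), function(id) {
    r <- ng86_kaks(pairs[[id]]$seq1, pairs[[id]]$seq2)
    data.frame(transcript_id = id, ka = r$ka, ks = r$ks, ratio = r$ratio,
               capped = r$capped)
  })
  do.call(rbind, rows)
}
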