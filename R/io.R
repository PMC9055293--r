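## Interchange formats --------------------------------------------------------

dosage_to_gt <- function(g) {
  out <- rep("./.", length(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

#' Write a SNP dataset as VCF
#'
#' One record per SNP (v4.2 dialect): `CHROM` is the locus id, `ID` is
#' `<locus>_<pos>` so readers can recover the locus grouping from the ID
#' prefix, the locus length travels in `INFO/LEN`, and genotypes are
#' diploid `GT` calls with `./.` for missing.
#'
#' @param dataset a [snp_dataset()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path) {
  n_snp <- nrow(dataset$geno)
  ind <- colnames(dataset$geno) %||%
    sprintf("%s_%d", as.character(dataset$pop), stats::ave(seq_along(dataset$pop),
            dataset$pop, FUN = seq_along))
  len <- dataset$loci$length_bp[match(dataset$locus, dataset$loci$locus_id)]
  pos_bp <- ifelse(is.na(dataset$position), seq_len(n_snp),
                   floor(dataset$position * ifelse(is.na(len), 1000, len)) + 1)
  ## strictly increasing positions within a locus
  for (l in unique(dataset$locus)) {
    i <- which(dataset$locus == l)
    if (length(i) > 1) pos_bp[i] <- cummax(c(pos_bp[i][1], pmax(pos_bp[i][-1],
                                             head(pos_bp[i], -1) + 1)))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=divabc",
    "##INFO=<ID=LEN,Number=1,Type=Integer,Description=\"Locus length in bp\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind), collapse = "\t")
  )
  gt <- apply(dataset$geno, 2, dosage_to_gt)
  if (n_snp == 1L) gt <- matrix(gt, nrow = 1)
  body <- if (n_snp) paste(
    dataset$locus, pos_bp, paste0(dataset$locus, "_", pos_bp), "A", "T", ".",
    "PASS", paste0("LEN=", ifelse(is.na(len), ".", len)), "GT",
    apply(gt, 1, paste, collapse = "\t"),
    sep = "\t") else character(0)
  writeLines(c(header, body), path)
  invisible(path)
}

gt_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1")] <- 2L
  known <- is.na(gt) | gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(!known))
    stop("malformed GT call(s): ", paste(unique(gt[!known]), collapse = ", "))
  out
}

#' Read a biallelic SNP VCF into a dataset
#'
#' Reads diploid `GT` calls (missing `./.` preserved) and groups SNPs into
#' loci either through an explicit locus map or from the ID prefix
#' (`locusN_pos`), falling back to `CHROM`.  Multi-allelic records are an
#' error under `multiallelic = "error"` (default) or removed under
#' `"drop"`.
#'
#' @param path VCF file.
#' @param popmap population map: a two-column data.frame
#'   (individual, population) or the path of a headerless TSV in that
#'   layout.  Every sample in the VCF must be present.
#' @param locus_map optional data.frame (`snp_id`, `locus_id`) overriding
#'   the ID-prefix convention.
#' @param multiallelic `"error"` or `"drop"`.
#' @return a [snp_dataset()].
#' @export
read_vcf <- function(path, popmap, locus_map = NULL,
                     multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multi-allelic record(s): ",
           paste(fix[multi, "ID"], collapse = ", "))
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  missing_ind <- setdiff(samples, popmap[[1]])
  if (length(missing_ind))
    stop("sample(s) absent from popmap: ", paste(missing_ind, collapse = ", "))
  pop <- popmap[[2]][match(samples, popmap[[1]])]
  geno <- apply(gt, 2, gt_to_dosage)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1,
                                         dimnames = list(NULL, samples))
  ids <- fix[, "ID"]
  locus <- if (!is.null(locus_map)) {
    lm <- locus_map[[2]][match(ids, locus_map[[1]])]
    if (anyNA(lm)) stop("locus_map does not cover all SNP ids")
    lm
  } else {
    ifelse(grepl("^.+_[^_]+$", ids), sub("_[^_]+$", "", ids), fix[, "CHROM"])
  }
  info <- fix[, "INFO"]
  len <- suppressWarnings(as.integer(sub(".*LEN=([0-9]+).*", "\\1",
                                         ifelse(grepl("LEN=", info), info, NA))))
  pos_bp <- as.numeric(fix[, "POS"])
  uloc <- unique(locus)
  loci <- data.frame(
    locus_id = uloc,
    length_bp = len[match(uloc, locus)],
    n_sites = as.integer(table(factor(locus, levels = uloc)))
  )
  colnames(geno) <- samples
  snp_dataset(geno = geno, locus = locus,
              position = ifelse(is.na(loci$length_bp[match(locus, uloc)]),
                                NA_real_,
                                (pos_bp - 1) / loci$length_bp[match(locus, uloc)]),
              loci = loci, pop = pop, provenance = "file")
}

#' Read / write a population map (Stacks popmap dialect)
#'
#' Headerless two-column TSV: individual, population.
#'
#' @param path TSV file.
#' @return data.frame with columns `individual`, `population`.
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("individual", "population"))
  pm
}

#' @rdname read_popmap
#' @param popmap data.frame (individual, population).
#' @export
write_popmap <- function(popmap, path) {
  write.table(popmap, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Persist / restore an ABC reference table
#'
#' TSV with `model`, parameter and statistic columns, plus a JSON sidecar
#' (`<path>.json`) recording the seeds and configuration used to build it.
#'
#' @param table a [build_reference_table()] result.
#' @param path TSV file.
#' @param config optional list stored in the sidecar.
#' @export
write_reference_table <- function(table, path, config = list()) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- c(list(package = "divabc",
                    version = as.character(utils::packageVersion("divabc")),
                    n_per_model = attr(table, "n_per_model")),
               config)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  class(tab) <- c("reference_table", "data.frame")
  tab
}

#' Read / write paired ortholog CDS FASTA files
#'
#' Two FASTA files with matching sequence ids (the ortholog-group key);
#' pairs are matched by id.
#'
#' @param pairs named list of `list(seq1, seq2)`.
#' @param path1,path2 FASTA files for the two species.
#' @export
write_cds_pairs <- function(pairs, path1, path2) {
  s1 <- Biostrings::DNAStringSet(vapply(pairs, function(p)
    as.character(p$seq1), character(1)))
  s2 <- Biostrings::DNAStringSet(vapply(pairs, function(p)
    as.character(p$seq2), character(1)))
  names(s1) <- names(s2) <- names(pairs)
  Biostrings::writeXStringSet(s1, path1)
  Biostrings::writeXStringSet(s2, path2)
  invisible(c(path1, path2))
}

#' @rdname write_cds_pairs
#' @export
read_cds_pairs <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1)
  s2 <- Biostrings::readDNAStringSet(path2)
  common <- intersect(names(s1), names(s2))
  if (!length(common)) stop("no shared ortholog ids between the two files")
  out <- lapply(common, function(id)
    list(seq1 = as.character(s1[[id]]), seq2 = as.character(s2[[id]])))
  names(out) <- common
  out
}

#' Write a reproducibility manifest
#'
#' JSON record of the configuration, seeds and package version that
#' produced a result artifact.
#'
#' @param path output JSON file.
#' @param ... named configuration entries (seeds, tolerances, inputs).
#' @export
write_manifest <- function(path, ...) {
  jsonlite::write_json(
    c(list(package = "divabc",
           version = as.character(utils::packageVersion("divabc")),
           r_version = as.character(getRversion()),
           date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      list(...)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
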