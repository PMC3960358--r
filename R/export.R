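#' Export genotypes as a marker-by-individual dosage matrix
#'
#' Tab-delimited text: one row per marker (with chromosome and cM position),
#' one column per individual, values 0/1/2 donor-allele dosage.
#'
#' @param pop An `il_pop` or `il_population`.
#' @param path Output file path.
#' @param map Genetic map; defaults to `pop$map`.
#' @param ids Column names for the individuals.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(pop, path, map = pop$map,
                            ids = paste0("IL", seq_len(pop$n))) {
  D <- t(pop$H1 + pop$H2)
  colnames(D) <- ids
  out <- cbind(data.frame(marker = seq_len(map$n_markers),
                          chrom = map$chrom, pos_cM = map$pos), D)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export genotypes as a minimal VCF
#'
#' Writes markers as pseudo-variants (REF `A` = recipient allele, ALT `T` =
#' donor allele) with GT fields, placing markers at integer base positions
#' `round(cM * 1e4)` on chromosomes `chr1..chrN`. Intended for quick
#' interoperability with VCF-consuming tools, not as a faithful physical
#' map.
#'
#' @inheritParams write_genotypes
#' @return `path`, invisibly.
#' @export
write_vcf <- function(pop, path, map = pop$map,
                      ids = paste0("IL", seq_len(pop$n))) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ilsim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  gt <- matrix(paste0(t(pop$H1), "/", t(pop$H2)),
               nrow = map$n_markers)
  body <- paste(paste0("chr", map$chrom),
                as.integer(round(map$pos * 1e4)),
                paste0("m", seq_len(map$n_markers)),
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write experiment outputs
#'
#' `write_measure_csv()` writes the rounded per-scheme measure table;
#' `write_replicates_csv()` the raw per-replicate measures; both are plain
#' CSV.
#'
#' @param x An `il_experiment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measure_csv <- function(x, path) {
  utils::write.csv(measure_table(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measure_csv
#' @export
write_replicates_csv <- function(x, path) {
  stopifnot(inherits(x, "il_experiment"))
  utils::write.csv(x$replicates, path, row.names = FALSE)
  invisible(path)
}
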