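#' Export offspring genotypes as a PLINK .raw-style table
#'
#' Tab-delimited with columns FID, IID, PAT, MAT, SEX and one column per
#' SNP counting effect alleles (`<snp>_<effect allele>` headers).
#'
#' @param population a `genpop`.
#' @param path output file.
#' @export
write_plink_raw <- function(population, path) {
  off <- population$offspring
  panel <- population$panel
  G <- population$G
  colnames(G) <- paste0(panel$snp, "_", panel$effect_allele)
  tab <- data.frame(
    FID = off$family_id,
    IID = off$id,
    PAT = paste0("F", off$father_id),
    MAT = paste0("M", off$mother_id),
    SEX = ifelse(off$sex == 1, 2L, 1L),
    G,
    check.names = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a 3-column PLINK score file
#'
#' Columns: variant id, effect allele, weight. Accepts an `snp_panel`
#' (score weights) or `fgwas_weights` (within-family estimates; a
#' companion `<path>.se` table with standard errors is written too).
#'
#' @param x an `snp_panel` or `fgwas_weights`.
#' @param path output file.
#' @export
write_score_file <- function(x, path) {
  if (inherits(x, "fgwas_weights")) {
    tab <- data.frame(x$snp, "A", x$beta)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(data.frame(x$snp, x$se), paste0(path, ".se"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    tab <- data.frame(x$snp, x$effect_allele, x$score_weight)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a 3-column PLINK score file
#' @param path file with columns variant id, effect allele, weight.
#' @return data frame `snp`, `effect_allele`, `weight`.
#' @export
read_score_file <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) != 3) stop("score file must have 3 columns", call. = FALSE)
  names(tab) <- c("snp", "effect_allele", "weight")
  tab
}

#' Write a GWAS summary-statistics table
#'
#' Tab-delimited columns SNP, EA, NEA, EAF, BETA_EXP, SE_EXP, BETA_OUT,
#' SE_OUT (the layout read back by [read_snp_summary()]).
#'
#' @param summary a `snp_summary`.
#' @param path output file.
#' @export
write_snp_summary <- function(summary, path) {
  tab <- data.frame(SNP = summary$snp, EA = summary$ea, NEA = summary$nea,
                    EAF = summary$eaf, BETA_EXP = summary$beta_exp,
                    SE_EXP = summary$se_exp, BETA_OUT = summary$beta_out,
                    SE_OUT = summary$se_out)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GWAS summary-statistics table
#' @param path tab-delimited file written by [write_snp_summary()] (columns
#'   SNP, EA, NEA, EAF, BETA_EXP, SE_EXP, BETA_OUT, SE_OUT).
#' @param harmonize orient alleles so exposure associations are
#'   nonnegative, default TRUE.
#' @return a `snp_summary` data frame.
#' @export
read_snp_summary <- function(path, harmonize = TRUE) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("SNP", "EA", "NEA", "EAF", "BETA_EXP", "SE_EXP", "BETA_OUT",
            "SE_OUT")
  missing <- setdiff(need, names(tab))
  if (length(missing)) stop("summary table lacks column(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(snp = tab$SNP, ea = tab$EA, nea = tab$NEA, eaf = tab$EAF,
                    beta_exp = tab$BETA_EXP, se_exp = tab$SE_EXP,
                    beta_out = tab$BETA_OUT, se_out = tab$SE_OUT,
                    stringsAsFactors = FALSE)
  if (harmonize) harmonize_summary(out) else {
    class(out) <- c("snp_summary", "data.frame")
    out
  }
}

#' Write an analysis sample as tab-delimited tables
#'
#' Writes the phenotype/covariate table (wide) and the long-format
#' earnings panel (`id`, `age`, `earnings`) if the sample carries one.
#'
#' @param sample an `analysis_sample`.
#' @param path base output path; the panel goes to `<path>_panel.tsv`.
#' @export
write_sample <- function(sample, path) {
  utils::write.table(sample$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sample$earnings)) {
    ages <- as.integer(colnames(sample$earnings))
    long <- data.frame(
      id = rep(sample$data$id, times = length(ages)),
      age = rep(ages, each = nrow(sample$earnings)),
      earnings = as.vector(sample$earnings)
    )
    utils::write.table(long, paste0(tools::file_path_sans_ext(path),
                                    "_panel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
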