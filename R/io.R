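#' Write a simulated cohort to disk (VCF v4.2 + TSVs)
#'
#' Emits `exome.vcf` (rare-variant genotypes with INFO tags `GENE`,
#' `CSQ_IMPACT`, `CSQ_CLASS`), `phenotypes.tsv` (covariates and standing
#' height), `sumstats.tsv` (GWAS weights input) and `chip_dosages.tsv`
#' (common-SNP dosage matrix). Plain text throughout, so every stage of
#' the pipeline is auditable with command-line tools.
#'
#' @param cohort a `best_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "best_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(dir, "exome.vcf"),
             pheno = file.path(dir, "phenotypes.tsv"),
             sumstats = file.path(dir, "sumstats.tsv"),
             chip = file.path(dir, "chip_dosages.tsv"))

  v <- cohort$variants
  n <- nrow(cohort$samples)
  gt_codes <- c("0/0", "0/1", "1/1")
  D <- as.matrix(Matrix::t(cohort$dosages))  # variants x samples
  gt <- matrix(gt_codes[D + 1], nrow = nrow(v))
  info <- sprintf("GENE=%s;CSQ_IMPACT=%s;CSQ_CLASS=%s",
                  v$gene, v$impact, v$consequence_class)
  body <- cbind(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                info, "GT", gt)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bestgene",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ_IMPACT,Number=1,Type=String,Description=\"Predicted impact\">",
    "##INFO=<ID=CSQ_CLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t")
  )
  con <- file(paths["vcf"], "w")
  writeLines(header, con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  close(con)

  utils::write.table(cohort$samples, paths["pheno"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$sumstats, paths["sumstats"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  chip <- data.frame(sample_id = cohort$samples$sample_id,
                     cohort$common_dosages, check.names = FALSE)
  utils::write.table(chip, paths["chip"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

info_field <- function(info, tag) {
  m <- regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  hit <- lengths(regmatches(info, regexpr(paste0("(^|;)", tag, "=[^;]*"),
                                          info))) > 0
  out[hit] <- sub(paste0(".*", tag, "="), "", m)
  out
}

#' Load a cohort from a VCF and a phenotype TSV
#'
#' Reads genotypes with `vcfR`, converts them to an alternate-allele
#' dosage matrix, and extracts the `GENE` / `CSQ_IMPACT` / `CSQ_CLASS`
#' INFO annotations. Multi-allelic records are rejected (pre-split them);
#' a missing `GENE` tag is an error. Phenotype rows without genotypes are
#' dropped with a message; genotyped samples without phenotypes are an
#' error listing the orphans.
#'
#' @param vcf_path path to a VCF v4.2 file.
#' @param pheno_path path to a phenotype/covariate TSV with a
#'   `sample_id` column.
#' @return a `best_cohort`-like list with `samples`, `variants`,
#'   `dosages`.
#' @export
load_cohort <- function(vcf_path, pheno_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic records found; pre-split them (e.g. bcftools norm)")
  }
  gene <- info_field(fix$INFO, "GENE")
  if (anyNA(gene)) stop("VCF INFO is missing the GENE tag")
  impact <- info_field(fix$INFO, "CSQ_IMPACT")
  cons <- info_field(fix$INFO, "CSQ_CLASS")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- matrix(0L, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), fix$ID))
  alt_count <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x)
    out[ok] <- vapply(strsplit(x[ok], "[/|]"),
                      function(a) sum(a == "1"), integer(1))
    out
  }
  for (i in seq_len(nrow(gt))) dos[, i] <- alt_count(gt[i, ])

  pheno <- utils::read.delim(pheno_path, check.names = FALSE)
  orphans <- setdiff(rownames(dos), pheno$sample_id)
  if (length(orphans) > 0) {
    stop("genotyped samples missing from phenotype file: ",
         paste(utils::head(orphans, 5), collapse = ", "))
  }
  extra <- setdiff(pheno$sample_id, rownames(dos))
  if (length(extra) > 0) {
    message(length(extra), " phenotype row(s) without genotypes dropped")
    pheno <- pheno[pheno$sample_id %in% rownames(dos), , drop = FALSE]
  }
  pheno <- pheno[match(rownames(dos), pheno$sample_id), , drop = FALSE]

  variants <- tibble::tibble(
    variant_id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, gene = gene,
    consequence_class = cons, impact = impact,
    cohort_ac = as.integer(colSums(dos, na.rm = TRUE)),
    cohort_an = 2L * as.integer(colSums(!is.na(dos)))
  )
  list(samples = tibble::as_tibble(pheno), variants = variants,
       dosages = Matrix::Matrix(dos, sparse = TRUE))
}
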