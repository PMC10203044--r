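## Readers/writers for the pipeline's plain-text dialects: VCF and dosage
## TSV for genotypes, GWAS-SSF-like TSV for summary statistics,
## PGS-Catalog-style scoring files for weights, fixed-column TSV for
## cohorts. All files are UTF-8, tab-separated, '.' for missing.

.ssf_out <- c(variant_id = "variant_id", chromosome = "chromosome",
              position = "position", effect_allele = "effect_allele",
              other_allele = "other_allele", beta = "beta",
              se = "standard_error", p = "p_value", n = "n",
              allele_frequency = "effect_allele_frequency")

#' Write summary statistics
#'
#' GWAS-SSF-like tab-separated text (`standard_error`, `p_value`,
#' `effect_allele_frequency` column names).
#'
#' @param sumstats a [SumStats-class].
#' @param file output path.
#' @export
writeSumStats <- function(sumstats, file) {
  df <- as.data.frame(sumstats)
  extra <- setdiff(colnames(df), names(.ssf_out))
  out <- df[, names(.ssf_out), drop = FALSE]
  colnames(out) <- unname(.ssf_out)
  if (length(extra)) out <- cbind(out, df[, extra, drop = FALSE])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(file)
}

#' Read summary statistics
#' @param file path to a tab-separated summary-statistics file.
#' @return a [SumStats-class]; unknown extra columns are preserved (with
#'   a message).
#' @export
readSumStats <- function(file) {
  df <- read.delim(file, na.strings = ".", stringsAsFactors = FALSE)
  ren <- setNames(names(.ssf_out), unname(.ssf_out))
  hit <- colnames(df) %in% names(ren)
  colnames(df)[hit] <- ren[colnames(df)[hit]]
  miss <- setdiff(names(.ssf_out), colnames(df))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(df), names(.ssf_out))
  if (length(extra))
    message("preserving extra columns: ", paste(extra, collapse = ", "))
  SumStats(df[, c(names(.ssf_out), extra), drop = FALSE])
}

#' Write a PGS scoring file
#'
#' PGS-Catalog-style: '#' header comments, then `rsID`, `chr_name`,
#' `effect_allele`, `effect_weight` columns.
#'
#' @param weights a [WeightVector-class].
#' @param file output path.
#' @export
writeWeights <- function(weights, file) {
  prov <- S4Vectors::metadata(weights)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("# PGS scoring file", con)
  for (nm in names(prov))
    writeLines(sprintf("# %s=%s", nm, prov[[nm]]), con)
  df <- as.data.frame(weights)
  out <- data.frame(rsID = df$variant_id, chr_name = df$chromosome,
                    effect_allele = df$effect_allele,
                    effect_weight = df$weight)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a PGS scoring file
#' @param file path to a scoring file written by [writeWeights()].
#' @return a [WeightVector-class]; '#' metadata is restored.
#' @export
readWeights <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines)
  prov <- list()
  for (h in lines[hdr]) {
    kv <- regmatches(h, regexec("^# ([^=]+)=(.*)$", h))[[1]]
    if (length(kv) == 3) prov[[kv[2]]] <- utils::type.convert(kv[3],
                                                              as.is = TRUE)
  }
  df <- read.delim(textConnection(lines[-hdr]), stringsAsFactors = FALSE)
  need <- c("rsID", "chr_name", "effect_allele", "effect_weight")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("missing mandatory columns: ", paste(miss, collapse = ", "))
  WeightVector(data.frame(variant_id = df$rsID,
                          chromosome = df$chr_name,
                          effect_allele = df$effect_allele,
                          weight = df$effect_weight,
                          stringsAsFactors = FALSE),
               provenance = prov)
}

#' Write a LOCO weight set as scoring files plus a JSON manifest
#' @param set a [LocoWeightSet-class].
#' @param dir output directory (created if needed).
#' @export
writeLocoWeightSet <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("loco_excl_chr%02d.txt", set@excluded)
  for (i in seq_along(set@weights))
    writeWeights(set@weights[[i]], file.path(dir, files[i]))
  jsonlite::write_json(
    list(excluded = set@excluded, files = files),
    file.path(dir, "manifest.json"), auto_unbox = FALSE)
  invisible(dir)
}

#' Read a LOCO weight set written by [writeLocoWeightSet()]
#' @param dir directory containing the manifest.
#' @export
readLocoWeightSet <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  LocoWeightSet(lapply(man$files,
                       function(f) readWeights(file.path(dir, f))),
                man$excluded)
}

#' Write a cohort table
#' @param cohort cohort data.frame.
#' @param file output path ('.' encodes missing).
#' @export
writeCohort <- function(cohort, file) {
  write.table(cohort, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(file)
}

#' Read a cohort table
#' @param file path written by [writeCohort()].
#' @export
readCohort <- function(file) {
  read.delim(file, na.strings = ".", stringsAsFactors = FALSE)
}

#' Write a genotype panel as VCF
#'
#' Minimal VCFv4.2 with a DS (dosage) FORMAT field; REF is the other
#' allele, ALT the effect allele, AF carried in INFO.
#'
#' @param panel a [GenotypePanel-class].
#' @param file output path (uncompressed).
#' @export
writeGenotypesVcf <- function(panel, file) {
  v <- variantInfo(panel)
  G <- dosageMatrix(panel)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", sampleIds(panel)), collapse = "\t")), con)
  body <- cbind(v$chromosome, v$position, v$variant_id, v$other_allele,
                v$effect_allele, ".", ".",
                sprintf("AF=%.6g", v$allele_frequency), "DS",
                matrix(sprintf("%.6g", G), nrow = nrow(G)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(file)
}

#' Write a panel as a dosage TSV
#'
#' Samples x variants, first column `sample_id`, header row of variant
#' ids; a companion variants TSV carries the variant metadata.
#'
#' @param panel a [GenotypePanel-class].
#' @param file dosage TSV path.
#' @param variants_file companion variant-metadata TSV path (default:
#'   `file` with a `.variants.tsv` suffix).
#' @export
writeDosageTsv <- function(panel, file,
                           variants_file = paste0(file, ".variants.tsv")) {
  G <- t(dosageMatrix(panel))
  df <- data.frame(sample_id = sampleIds(panel), G, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(variantInfo(panel), variants_file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read genotypes
#'
#' VCF (DS field used when present, otherwise GT converted to alt-allele
#' count; mixed ploidy rejected) or dosage TSV with its companion
#' variants file. Variants are returned sorted by (chromosome, position).
#'
#' @param path input path.
#' @param format "vcf" or "dosage".
#' @param variants_file companion metadata TSV for `format = "dosage"`.
#' @return a [GenotypePanel-class].
#' @export
readGenotypes <- function(path, format = c("vcf", "dosage"),
                          variants_file = paste0(path, ".variants.tsv")) {
  format <- match.arg(format)
  if (format == "dosage") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    v <- read.delim(variants_file, stringsAsFactors = FALSE)
    G <- t(as.matrix(df[, -1, drop = FALSE]))
    v <- v[match(rownames(G), v$variant_id), , drop = FALSE]
    o <- order(v$chromosome, v$position)
    return(GenotypePanel(G[o, , drop = FALSE], v[o, , drop = FALSE],
                         df$sample_id))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  fmt <- unique(vcf@gt[, "FORMAT"])
  has_ds <- any(grepl("DS", fmt))
  if (has_ds) {
    G <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    alleles <- gsub("[/|]", "", gt)
    if (any(nchar(alleles) != 2, na.rm = TRUE))
      stop("mixed ploidy is not supported")
    G <- matrix(vapply(strsplit(gt, "[/|]"),
                       function(a) sum(a == "1"), numeric(1)),
                nrow = nrow(gt), dimnames = dimnames(gt))
  }
  af <- suppressWarnings(
    as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1", fix[, "INFO"])))
  if (anyNA(af)) af <- rowMeans(G, na.rm = TRUE) / 2
  v <- data.frame(chromosome = as.integer(fix[, "CHROM"]),
                  position = as.integer(fix[, "POS"]),
                  variant_id = fix[, "ID"],
                  effect_allele = fix[, "ALT"],
                  other_allele = fix[, "REF"],
                  allele_frequency = af, stringsAsFactors = FALSE)
  o <- order(v$chromosome, v$position)
  GenotypePanel(G[o, , drop = FALSE], v[o, , drop = FALSE],
                colnames(G))
}
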