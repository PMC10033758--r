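# MAF (Mutation Annotation Format) ingestion and writing. Required
# columns follow the standard dialect; "#"-prefixed lines are comments.

maf_required_cols <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                       "End_Position", "Reference_Allele",
                       "Tumor_Seq_Allele2", "Variant_Classification",
                       "Variant_Type", "Tumor_Sample_Barcode")

validate_maf_records <- function(maf, where = "MAF") {
  bases <- c("A", "C", "G", "T")
  snp <- maf$Variant_Type == "SNP"
  bad_snp <- snp & (!(maf$Reference_Allele %in% bases) |
                    !(maf$Tumor_Seq_Allele2 %in% bases) |
                    maf$Reference_Allele == maf$Tumor_Seq_Allele2)
  bad_ins <- maf$Variant_Type == "INS" & maf$Reference_Allele != "-"
  bad_del <- maf$Variant_Type == "DEL" & maf$Tumor_Seq_Allele2 != "-"
  bad_pos <- maf$Start_Position > maf$End_Position
  bad <- which(bad_snp | bad_ins | bad_del | bad_pos)
  if (length(bad))
    stop(where, ": invalid record at line ", bad[1] + 1L,
         " (1-based, counting the header): ",
         if (bad[1] %in% which(bad_snp)) "SNP alleles must be distinct single bases"
         else if (bad[1] %in% which(bad_pos)) "start must be <= end"
         else "INS requires ref '-', DEL requires alt '-'",
         call. = FALSE)
  invisible(maf)
}

#' Read a MAF file
#'
#' Tab-separated with a header row; lines starting with `#` are skipped.
#' Unknown extra columns are preserved.
#'
#' @param path Path to the MAF file.
#' @return Data.frame of variant records.
#' @export
read_maf <- function(path) {
  maf <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  missing <- setdiff(maf_required_cols, names(maf))
  if (length(missing))
    stop("MAF '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  maf$Chromosome <- as.character(maf$Chromosome)
  maf$Start_Position <- as.integer(maf$Start_Position)
  maf$End_Position <- as.integer(maf$End_Position)
  validate_maf_records(maf, where = path)
  maf
}

#' Write a MAF file
#'
#' Writes the required columns tab-separated; extra columns are dropped
#' with a warning.
#'
#' @param maf Data.frame of variant records.
#' @param path Output path.
#' @export
write_maf <- function(maf, path) {
  missing <- setdiff(maf_required_cols, names(maf))
  if (length(missing))
    stop("records are missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(maf), maf_required_cols)
  if (length(extra))
    warning("dropping non-standard column(s) on write: ",
            paste(extra, collapse = ", "), call. = FALSE)
  utils::write.table(maf[, maf_required_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Identity key of a variant call: position and alleles, not annotations,
# so annotation drift cannot break paired subtraction.
maf_key <- function(maf) {
  paste(maf$Chromosome, maf$Start_Position, maf$End_Position,
        maf$Reference_Allele, maf$Tumor_Seq_Allele2, maf$Variant_Type,
        sep = "\r")
}

#' Hypoxia-private variants of one matched pair
#'
#' Returns the hypoxia records whose identity key (chromosome, start,
#' end, ref allele, alt allele, variant type) is absent from the matched
#' normoxia sample, i.e. the mutations that emerged only under hypoxia.
#' Duplicate keys within one sample are collapsed with a warning before
#' subtraction; output order is stable by (chromosome, start).
#'
#' @param hypoxia,normoxia MAF data.frames of the two samples of a pair.
#' @return Data.frame of hypoxia-only records.
#' @export
subtract_paired <- function(hypoxia, normoxia) {
  hk <- maf_key(hypoxia)
  if (anyDuplicated(hk)) {
    warning("collapsing ", sum(duplicated(hk)),
            " duplicate record(s) in hypoxia sample", call. = FALSE)
    hypoxia <- hypoxia[!duplicated(hk), , drop = FALSE]
    hk <- hk[!duplicated(hk)]
  }
  nk <- unique(maf_key(normoxia))
  out <- hypoxia[!(hk %in% nk), , drop = FALSE]
  out <- out[order(out$Chromosome, out$Start_Position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tumor mutational burden
#'
#' @param records MAF data.frame of retained (hypoxia-private) variants.
#' @param exome_size_mb Sequenced footprint in megabases (> 0); default
#'   57.7, the design size of the exome panel.
#' @param nonsilent_only If `TRUE`, Silent variants are excluded from the
#'   count.
#' @return Mutations per megabase.
#' @export
compute_tmb <- function(records, exome_size_mb = 57.7,
                        nonsilent_only = FALSE) {
  if (!is.finite(exome_size_mb) || exome_size_mb <= 0)
    stop("exome_size_mb must be positive", call. = FALSE)
  n <- if (nonsilent_only)
    sum(records$Variant_Classification != "Silent") else nrow(records)
  n / exome_size_mb
}

#' Six-class SNV label and transition/transversion status
#'
#' Purine-reference substitutions are folded onto the pyrimidine-
#' reference strand (standard six-class convention); transitions are
#' `C>T` and `T>C`.
#'
#' @param ref,alt Single-base alleles (vectorized).
#' @return Data.frame with columns `class` (one of C>A, C>G, C>T, T>A,
#'   T>C, T>G) and `type` ("transition"/"transversion").
#' @examples
#' classify_snv("G", "A")  # C>T, transition
#' @export
classify_snv <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (any(!ref %in% bases) || any(!alt %in% bases) || any(ref == alt))
    stop("SNV alleles must be distinct single bases", call. = FALSE)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, comp[ref], ref)
  a <- ifelse(purine, comp[alt], alt)
  cls <- paste0(r, ">", a)
  data.frame(class = cls,
             type = ifelse(cls %in% c("C>T", "T>C"),
                           "transition", "transversion"),
             stringsAsFactors = FALSE)
}
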