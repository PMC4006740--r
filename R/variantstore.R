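#' Variant key strings
#'
#' Variant identity is (chromosome, position, ref, alt) after multi-allelic
#' splitting, rendered `"chrom:pos:ref:alt"`. Coordinates are 1-based,
#' fully closed, per VCF convention.
#'
#' @param chrom,pos,ref,alt Vectors of equal length.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, format(pos, scientific = FALSE, trim = TRUE), ref, alt,
        sep = ":")
}

# Inverse of variant_key for panel/db serialization.
key_to_fields <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    ref = vapply(parts, `[`, character(1), 3),
    alt = vapply(parts, `[`, character(1), 4),
    stringsAsFactors = FALSE
  )
}

#' Construct a genotype matrix
#'
#' Biallelic genotype calls per variant per sample, coded as the count of
#' alternate alleles: 0 = hom ref, 1 = het, 2 = hom alt, `NA` = missing.
#'
#' @param sites Data frame with columns chrom, pos, ref, alt.
#' @param geno Integer matrix, `nrow(sites)` rows, one column per sample
#'   (column names are sample ids).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, geno) {
  stopifnot(nrow(sites) == nrow(geno), !is.null(colnames(geno)))
  sites <- sites[, c("chrom", "pos", "ref", "alt")]
  rownames(sites) <- NULL
  sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  structure(list(sites = sites, geno = geno, samples = colnames(geno)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$sites), "variants x",
      length(x$samples), "samples\n")
  cat("  samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by sample
#' @param gm A `genotype_matrix`.
#' @param samples Sample ids to keep.
#' @return A `genotype_matrix`.
#' @export
subset_samples <- function(gm, samples) {
  missing <- setdiff(samples, gm$samples)
  if (length(missing) > 0) {
    stop("sample(s) absent from genotype matrix: ",
         paste(missing, collapse = ", "))
  }
  genotype_matrix(gm$sites, gm$geno[, samples, drop = FALSE])
}

# Recode one diploid GT string vector against alternate-allele index k:
# state = number of alleles equal to k; any missing allele index => NA.
recode_gt <- function(gt, k) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) != 2 || anyNA(p) || any(p == ".")) return(NA_integer_)
    sum(p == as.character(k))
  }, integer(1))
}

#' Read genotypes from a VCF file
#'
#' Parses diploid GT calls (phased or unphased separators); `./.` becomes
#' missing. Multi-allelic records are split into one variant key per
#' alternate allele, with genotype states recoded per alternate (e.g. a
#' `1/2` call at a triallelic site is heterozygous for each alternate).
#'
#' @param path Path to a VCFv4 file with a GT FORMAT field.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(v@gt) > 0 && !all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))) {
    stop("VCF record without GT in FORMAT: ", path)
  }
  gt <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(v@gt)[-1]))
  samples <- colnames(gt)
  out_sites <- list(); out_geno <- list(); n_out <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      n_out <- n_out + 1L
      out_sites[[n_out]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k], stringsAsFactors = FALSE)
      out_geno[[n_out]] <- recode_gt(gt[i, ], k)
    }
  }
  sites <- do.call(rbind, out_sites)
  geno <- do.call(rbind, out_geno)
  colnames(geno) <- samples
  genotype_matrix(sites, geno)
}

#' Write a genotype matrix as VCFv4.2
#'
#' Minimal GT-only records; output is plain text and byte-deterministic.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  geno_chr <- matrix(gt_str[gm$geno + 1L], nrow = nrow(gm$geno))
  geno_chr[is.na(gm$geno)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=homsift",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  body <- paste(
    gm$sites$chrom,
    format(gm$sites$pos, scientific = FALSE, trim = TRUE),
    ".", gm$sites$ref, gm$sites$alt, ".", "PASS", ".", "GT",
    apply(geno_chr, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  if (nrow(gm$sites) == 0) body <- character(0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a variant annotation table
#'
#' TSV with columns chrom, pos, ref, alt, gene, region_class,
#' effect_class, cds_pos and one column per predictor score.
#'
#' @param path Path to the TSV.
#' @return Data frame with an added `key` column.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt", "gene", "region_class",
           "effect_class")
  if (!all(req %in% names(df))) {
    stop("annotation table missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Read a population frequency table
#'
#' TSV with columns chrom, pos, ref, alt, freq (may be NA: no frequency
#' information) and pathogenic (logical: reported pathogenic allele).
#'
#' @param path Path to the TSV.
#' @return Data frame with an added `key` column.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  req <- c("chrom", "pos", "ref", "alt", "freq", "pathogenic")
  if (!all(req %in% names(df))) {
    stop("frequency table missing columns: ",
         paste(setdiff(req, names(df)), collapse = ", "))
  }
  df$pathogenic <- as.logical(df$pathogenic)
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  df
}

#' Build the exclusion database of common non-pathogenic variants
#'
#' A frequency record becomes a member exactly when it is not flagged
#' pathogenic, has frequency information, and that frequency is at least
#' 1% (the removal rule strips pathogenic alleles, variants below 1%, and
#' variants without any frequency information; "lower than 1%" removed
#' means exactly 1% is retained).
#'
#' @param records Frequency data frame as from [read_frequency_table()].
#' @param min_freq Membership frequency threshold (default 0.01).
#' @return An object of class `exclusion_db`.
#' @export
build_exclusion_db <- function(records, min_freq = 0.01) {
  keep <- !is.na(records$freq) & records$freq >= min_freq &
    !records$pathogenic
  keys <- if ("key" %in% names(records)) records$key else
    variant_key(records$chrom, records$pos, records$ref, records$alt)
  structure(list(keys = unique(keys[keep]), min_freq = min_freq),
            class = c("exclusion_db", "homsift_keyset"))
}

#' Build the in-house control panel
#'
#' The set of variant keys homozygous for the alternate allele in at least
#' one control individual.
#'
#' @param gm A `genotype_matrix` of control samples (or list of them).
#' @return An object of class `control_panel`.
#' @export
build_control_panel <- function(gm) {
  if (inherits(gm, "genotype_matrix")) gm <- list(gm)
  keys <- unlist(lapply(gm, function(g) {
    hom <- rowSums(g$geno == 2L, na.rm = TRUE) > 0
    g$sites$key[hom]
  }))
  structure(list(keys = sort(unique(keys))),
            class = c("control_panel", "homsift_keyset"))
}

#' Membership test for key sets
#' @param set An `exclusion_db` or `control_panel`.
#' @param keys Character vector of variant keys.
#' @return Logical vector.
#' @export
set_contains <- function(set, keys) keys %in% set$keys

#' @export
length.homsift_keyset <- function(x) length(x$keys)

#' @export
print.homsift_keyset <- function(x, ...) {
  cat(class(x)[1], "with", length(x$keys), "variant keys\n")
  invisible(x)
}

#' Read a control panel TSV (chrom, pos, ref, alt)
#' @param path Path to the TSV.
#' @return A `control_panel`.
#' @export
read_control_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(keys = sort(unique(
    variant_key(df$chrom, df$pos, df$ref, df$alt)))),
    class = c("control_panel", "homsift_keyset"))
}
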