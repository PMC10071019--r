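#' Variant panel: the SNP definition set for the CYP2C cluster
#'
#' A variant panel is an ordered table of biallelic SNP definitions over which
#' haplotypes are expressed. Each SNP is either a `cyp2c_site` (one of the two
#' CYP2C18 SNPs whose alleles spell the two-letter CYP2C haplotype label) or a
#' `star_site` (a CYP2C19 SNP whose variant allele defines a star allele).
#' The row order of the panel is the canonical coordinate order for every
#' haplotype allele vector produced downstream.
#'
#' @param snps A data.frame with columns `rsid`, `chrom`, `pos` (1-based,
#'   GRCh38), `ref`, `alt` (single bases), `gene`, `role` (one of
#'   `"cyp2c_site"`, `"star_site"`), and `star_tag` (e.g. `"*2"`; `NA` for
#'   cyp2c sites).
#' @return An object of class `variant_panel` (a validated data.frame).
#' @export
variant_panel <- function(snps) {
  required <- c("rsid", "chrom", "pos", "ref", "alt", "gene", "role", "star_tag")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("panel config is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  snps <- as.data.frame(snps)[, required]
  snps$pos <- as.integer(snps$pos)
  snps$star_tag <- ifelse(is.na(snps$star_tag) | snps$star_tag == "", NA_character_,
                          as.character(snps$star_tag))
  if (anyDuplicated(snps$rsid)) {
    stop("duplicate rsid in panel: ",
         paste(unique(snps$rsid[duplicated(snps$rsid)]), collapse = ", "))
  }
  if (any(is.na(snps$pos)) || any(snps$pos <= 0)) stop("malformed coordinates: pos must be a positive integer")
  bases <- c("A", "C", "G", "T")
  if (!all(snps$ref %in% bases) || !all(snps$alt %in% bases)) {
    stop("ref/alt alleles must be single bases (A/C/G/T)")
  }
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  if (!all(snps$role %in% c("cyp2c_site", "star_site"))) {
    stop("role must be 'cyp2c_site' or 'star_site'")
  }
  star <- snps$role == "star_site"
  if (any(star & is.na(snps$star_tag))) stop("star_site without star_tag")
  if (any(!star & !is.na(snps$star_tag))) stop("cyp2c_site must not carry a star_tag")
  n_cyp2c <- sum(!star)
  if (n_cyp2c != 2) stop("panel must contain exactly 2 cyp2c_sites, got ", n_cyp2c)
  rownames(snps) <- NULL
  class(snps) <- c("variant_panel", "data.frame")
  snps
}

#' Built-in six-SNP (or subset) CYP2C-cluster panel
#'
#' The default panel covers rs2860840 and rs11188059 in CYP2C18 (the two
#' CYP2C haplotype sites) and four CYP2C19 star-allele sites: rs4244285 (*2),
#' rs4986893 (*3), rs17884712 (*9) and rs12248560 (*17), all on GRCh38.
#' Cohorts genotyped at fewer loci (e.g. the 4-SNP design without *3 and *9)
#' are handled by subsetting with `loci`.
#'
#' @param loci Optional character vector of rsids to retain (the two
#'   cyp2c sites must be among them).
#' @return A [variant_panel].
#' @examples
#' default_panel()
#' default_panel(loci = c("rs2860840", "rs11188059", "rs4244285", "rs12248560"))
#' @export
default_panel <- function(loci = NULL) {
  snps <- data.frame(
    rsid = c("rs2860840", "rs11188059", "rs4244285", "rs4986893",
             "rs17884712", "rs12248560"),
    chrom = "chr10",
    pos = c(94735475L, 94709142L, 94781859L, 94780653L, 94775489L, 94761900L),
    ref = c("C", "G", "G", "G", "G", "C"),
    alt = c("T", "A", "A", "A", "A", "T"),
    gene = c("CYP2C18", "CYP2C18", "CYP2C19", "CYP2C19", "CYP2C19", "CYP2C19"),
    role = c("cyp2c_site", "cyp2c_site", rep("star_site", 4)),
    star_tag = c(NA, NA, "*2", "*3", "*9", "*17"),
    stringsAsFactors = FALSE
  )
  if (!is.null(loci)) {
    unknown <- setdiff(loci, snps$rsid)
    if (length(unknown) > 0) stop("unknown rsid(s): ", paste(unknown, collapse = ", "))
    snps <- snps[snps$rsid %in% loci, , drop = FALSE]
  }
  variant_panel(snps)
}

#' Load a variant panel from a TSV or JSON config file
#'
#' TSV configs have a header row with the [variant_panel] column names;
#' JSON configs are an array of objects with the same fields. A missing or
#' empty `star_tag` denotes a cyp2c site.
#'
#' @param path Path to the config file; format is inferred from the extension
#'   (`.json` vs anything else = TSV).
#' @return A [variant_panel].
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel config not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (!"star_tag" %in% names(df)) df$star_tag <- NA_character_
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!"star_tag" %in% names(df)) df$star_tag <- NA_character_
  }
  variant_panel(df)
}

#' @export
print.variant_panel <- function(x, ...) {
  cat("variant_panel with", nrow(x), "SNPs (",
      sum(x$role == "cyp2c_site"), "CYP2C sites,",
      sum(x$role == "star_site"), "star sites )\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' @rdname variant_panel
#' @param panel A [variant_panel].
#' @return `cyp2c_sites()`/`star_sites()`: the matching panel rows;
#'   `cyp2c_sites()` always orders rs2860840 before rs11188059, the fixed
#'   order in which the two alleles are concatenated into the TG/TA/CG/CA
#'   label.
#' @export
cyp2c_sites <- function(panel) {
  s <- panel[panel$role == "cyp2c_site", , drop = FALSE]
  # fixed label order: rs2860840 letter first, rs11188059 second
  s[order(match(s$rsid, c("rs2860840", "rs11188059"))), , drop = FALSE]
}

#' @rdname variant_panel
#' @export
star_sites <- function(panel) {
  panel[panel$role == "star_site", , drop = FALSE]
}
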