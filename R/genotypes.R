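#' Unphased genotype matrix over a variant panel
#'
#' Calls are stored as unordered allele pairs `"X/Y"` (alleles sorted so that
#' `"C/T"` and `"T/C"` are the same call) or `NA` for missing. Columns follow
#' panel order; phase separators in input VCFs are ignored because phase is
#' what the pipeline infers.
#'
#' @param calls Character matrix (samples x panel SNPs) of `"X/Y"` calls or
#'   `NA`; rownames are sample ids, colnames are rsids in panel order.
#' @param panel The [variant_panel] the columns refer to.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(calls, panel) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls))) stop("calls must have sample ids as rownames")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids")
  if (ncol(calls) != nrow(panel)) {
    stop("calls has ", ncol(calls), " columns but panel has ", nrow(panel), " SNPs")
  }
  colnames(calls) <- panel$rsid
  for (j in seq_len(ncol(calls))) {
    ok <- !is.na(calls[, j]) & calls[, j] != "."
    calls[!ok, j] <- NA_character_
    if (!any(ok)) next
    parts <- strsplit(calls[ok, j], "[/|]")
    bad_len <- vapply(parts, length, 1L) != 2L
    if (any(bad_len)) stop("malformed call at ", panel$rsid[j])
    al <- c(panel$ref[j], panel$alt[j])
    alleles <- vapply(parts, function(p) {
      if (!all(p %in% al)) {
        stop("call uses alleles outside {", al[1], ",", al[2], "} at ",
             panel$rsid[j], ": ", paste(p, collapse = "/"))
      }
      paste(sort(p), collapse = "/")
    }, character(1))
    calls[ok, j] <- alleles
  }
  structure(list(calls = calls, panel = panel), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "samples x", ncol(x$calls), "SNPs\n")
  print(utils::head(x$calls), ...)
  invisible(x)
}

#' @rdname genotype_matrix
#' @param gm A `genotype_matrix`.
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' Number of samples in a genotype matrix
#' @param gm A [genotype_matrix].
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' Read unphased genotypes from a TSV or VCF file
#'
#' TSV dialect: a header line `sample<TAB>rsid1<TAB>rsid2...`, one row per
#' sample, calls written `X/Y` or `.` for missing. VCF input (4.2+, GRCh38)
#' is restricted to biallelic SNVs; records are matched to the panel by
#' (chrom, pos, ref, alt) with rsid as fallback, and panel SNPs absent from
#' the file become missing for all samples. Strand is taken as given.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param panel The [variant_panel] to read against.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), panel) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "tsv") read_genotypes_tsv(path, panel) else read_genotypes_vcf(path, panel)
}

read_genotypes_tsv <- function(path, panel) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("empty genotype file: ", path)
  if (names(df)[1] != "sample") stop("TSV genotype file must start with a 'sample' column")
  if (anyDuplicated(df$sample)) stop("sample parsed twice: ",
                                     paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  calls <- matrix(NA_character_, nrow = nrow(df), ncol = nrow(panel),
                  dimnames = list(df$sample, panel$rsid))
  present <- intersect(panel$rsid, names(df))
  for (rs in present) calls[, rs] <- df[[rs]]
  genotype_matrix(calls, panel)
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files drop to a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(fix),
                                   dimnames = list(NULL, names(gt)))
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no sample genotype columns")
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("sample parsed twice in VCF header")
  calls <- matrix(NA_character_, nrow = length(samples), ncol = nrow(panel),
                  dimnames = list(samples, panel$rsid))
  chrom_norm <- function(x) sub("^chr", "", x)
  for (i in seq_len(nrow(fix))) {
    hit <- which(chrom_norm(panel$chrom) == chrom_norm(fix$CHROM[i]) &
                 panel$pos == as.integer(fix$POS[i]))
    if (length(hit) == 0 && !is.na(fix$ID[i])) hit <- which(panel$rsid == fix$ID[i])
    if (length(hit) == 0) next
    hit <- hit[1]
    if (nchar(fix$REF[i]) != 1 || nchar(fix$ALT[i]) != 1 || grepl(",", fix$ALT[i])) {
      stop("record at ", fix$CHROM[i], ":", fix$POS[i], " is not a biallelic SNV")
    }
    if (fix$REF[i] != panel$ref[hit] || fix$ALT[i] != panel$alt[hit]) {
      stop("allele mismatch at ", fix$CHROM[i], ":", fix$POS[i], ": VCF ",
           fix$REF[i], "/", fix$ALT[i], " vs panel ",
           panel$ref[hit], "/", panel$alt[hit])
    }
    al <- c(panel$ref[hit], panel$alt[hit])
    g <- gt[i, ]
    idx <- strsplit(ifelse(is.na(g), "./.", g), "[/|]")
    calls[, hit] <- vapply(idx, function(p) {
      if (length(p) != 2 || any(p == ".")) return(NA_character_)
      paste(sort(al[as.integer(p) + 1L]), collapse = "/")
    }, character(1))
  }
  genotype_matrix(calls, panel)
}

#' Write a genotype matrix to TSV or VCF
#'
#' Both formats round-trip through [read_genotypes()] call-for-call. The VCF
#' writer emits a minimal VCF 4.2 file with unphased `GT` fields (`/`
#' separator) and records in panel order.
#'
#' @param gm A [genotype_matrix].
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  panel <- gm$panel
  if (format == "tsv") {
    out <- data.frame(sample = sample_ids(gm), stringsAsFactors = FALSE)
    for (j in seq_len(nrow(panel))) {
      out[[panel$rsid[j]]] <- ifelse(is.na(gm$calls[, j]), ".", gm$calls[, j])
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  samples <- sample_ids(gm)
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh38",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  recs <- vapply(seq_len(nrow(panel)), function(j) {
    al <- c(panel$ref[j], panel$alt[j])
    gts <- vapply(gm$calls[, j], function(call) {
      if (is.na(call)) return("./.")
      p <- strsplit(call, "/")[[1]]
      paste(sort(match(p, al) - 1L), collapse = "/")
    }, character(1))
    paste(c(panel$chrom[j], panel$pos[j], panel$rsid[j], al[1], al[2],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Per-SNP genotype counts (ref-hom, het, alt-hom)
#'
#' @param gm A [genotype_matrix].
#' @param rsid SNP to count.
#' @return A `genotype_counts` list with `n_ref_hom`, `n_het`, `n_alt_hom`
#'   (missing calls are skipped).
#' @export
genotype_counts <- function(gm, rsid) {
  j <- match(rsid, gm$panel$rsid)
  if (is.na(j)) stop("rsid not in panel: ", rsid)
  al <- c(gm$panel$ref[j], gm$panel$alt[j])
  hom_ref <- paste(sort(c(al[1], al[1])), collapse = "/")
  hom_alt <- paste(sort(c(al[2], al[2])), collapse = "/")
  het <- paste(sort(al), collapse = "/")
  x <- gm$calls[, j]
  x <- x[!is.na(x)]
  structure(list(n_ref_hom = sum(x == hom_ref), n_het = sum(x == het),
                 n_alt_hom = sum(x == hom_alt)), class = "genotype_counts")
}
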