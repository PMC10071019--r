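#' Default star-allele definition table
#'
#' Star-allele definitions are data, not code: a table mapping each defining
#' variant to its star tag, so alternative nomenclatures can be swapped in.
#' The default encodes *2 = rs4244285 A, *3 = rs4986893 A, *9 = rs17884712 A,
#' *17 = rs12248560 T; *1 is never listed because it is assigned by default
#' when no defining variant allele is present.
#'
#' @return data.frame with columns `rsid`, `variant_allele`, `star_tag`.
#' @export
default_star_defs <- function() {
  data.frame(
    rsid = c("rs4244285", "rs4986893", "rs17884712", "rs12248560"),
    variant_allele = c("A", "A", "A", "T"),
    star_tag = c("*2", "*3", "*9", "*17"),
    stringsAsFactors = FALSE
  )
}

#' Load a star-allele definition table from TSV or JSON
#' @param path File with columns/fields `rsid`, `variant_allele`, `star_tag`.
#' @return data.frame as in [default_star_defs()].
#' @export
load_star_defs <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  }
  req <- c("rsid", "variant_allele", "star_tag")
  if (!all(req %in% names(df))) stop("star definition table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$rsid)) stop("duplicate rsid in star definitions")
  df[, req]
}

hap_allele_at <- function(hap, panel, rsid) {
  j <- match(rsid, panel$rsid)
  if (is.na(j)) return(NA_character_)
  substr(hap, j, j)
}

#' Two-letter CYP2C haplotype label (TG/TA/CG/CA)
#'
#' Concatenates the haplotype's alleles at the two CYP2C18 sites in fixed
#' order: rs2860840 letter first (C or T), rs11188059 second (G or A).
#'
#' @param hap Haplotype allele string in panel order.
#' @param panel The [variant_panel].
#' @return One of `"TG"`, `"TA"`, `"CG"`, `"CA"`.
#' @export
name_cyp2c <- function(hap, panel) {
  sites <- cyp2c_sites(panel)
  paste0(hap_allele_at(hap, panel, sites$rsid[1]),
         hap_allele_at(hap, panel, sites$rsid[2]))
}

#' Call the CYP2C19 star allele of a haplotype
#'
#' *1 (wild type) is assigned by default, i.e. when no variant allele is
#' present at any genotyped star site. A haplotype carrying two or more
#' defining variants is flagged as a conflict rather than silently collapsed
#' to a single tag.
#'
#' @param hap Haplotype allele string in panel order.
#' @param panel The [variant_panel].
#' @param star_defs Star definition table ([default_star_defs()]).
#' @return list with `star` (e.g. `"*2"`, or `NA` on conflict) and `conflict`.
#' @export
call_star <- function(hap, panel, star_defs = default_star_defs()) {
  defs <- star_defs[star_defs$rsid %in% panel$rsid, , drop = FALSE]
  hit <- vapply(seq_len(nrow(defs)), function(k) {
    identical(hap_allele_at(hap, panel, defs$rsid[k]), defs$variant_allele[k])
  }, logical(1))
  tags <- defs$star_tag[hit]
  if (length(tags) == 0) return(list(star = "*1", conflict = FALSE))
  if (length(tags) == 1) return(list(star = tags, conflict = FALSE))
  list(star = NA_character_, conflict = TRUE, tags = tags)
}

#' Combined CYP2C19-CYP2C haplotype label (e.g. "*1TG")
#'
#' Pairs the star allele with the two-letter CYP2C label. In the study
#' populations the TG haplotype is never linked to the *2 or *17 defining
#' variants; a TG label combined with a non-*1 star allele is therefore
#' rendered but flagged as a linkage violation.
#'
#' @inheritParams call_star
#' @return list with `label` (e.g. `"*1TG"`), `star`, `cyp2c`, `conflict`,
#'   `linkage_violation`.
#' @export
combined_label <- function(hap, panel, star_defs = default_star_defs()) {
  st <- call_star(hap, panel, star_defs)
  cy <- name_cyp2c(hap, panel)
  if (st$conflict) {
    return(list(label = NA_character_, star = NA_character_, cyp2c = cy,
                conflict = TRUE, linkage_violation = FALSE))
  }
  viol <- cy == "TG" && st$star != "*1"
  list(label = paste0(st$star, cy), star = st$star, cyp2c = cy,
       conflict = FALSE, linkage_violation = viol)
}

#' Merged analysis class of a combined label
#'
#' The *1CG and *1TA haplotypes carry the same (normal) activity and are
#' merged into one class for the diplotype and phenotype analyses; every
#' other combined label maps to itself.
#'
#' @param label Combined label string (e.g. `"*1TA"`).
#' @return The merged class (e.g. `"*1CG-or-TA"`).
#' @export
merge_class <- function(label) {
  ifelse(label %in% c("*1CG", "*1TA"), "*1CG-or-TA", label)
}

#' Label a set of haplotypes at every naming level
#'
#' @param haps Character vector of haplotype allele strings.
#' @param panel The [variant_panel].
#' @param star_defs Star definition table.
#' @return data.frame: `haplotype`, `cyp2c`, `star`, `combined`, `merged`,
#'   `conflict`, `linkage_violation`.
#' @export
label_haplotypes <- function(haps, panel, star_defs = default_star_defs()) {
  rows <- lapply(haps, function(h) {
    cl <- combined_label(h, panel, star_defs)
    data.frame(haplotype = h, cyp2c = cl$cyp2c,
               star = ifelse(cl$conflict, NA_character_, cl$star),
               combined = ifelse(cl$conflict, NA_character_, cl$label),
               merged = ifelse(cl$conflict, NA_character_, merge_class(cl$label)),
               conflict = cl$conflict, linkage_violation = cl$linkage_violation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expand a haplotype label to a full allele string over a panel
#'
#' Accepts either a two-letter CYP2C label (`"TG"`; star sites, if present in
#' the panel, are set to reference) or a combined label (`"*2CG"`; the star
#' allele's defining variant is set, all other star sites reference).
#'
#' @param label Label string.
#' @param panel The [variant_panel].
#' @param star_defs Star definition table.
#' @return Haplotype allele string in panel order.
#' @export
expand_label <- function(label, panel, star_defs = default_star_defs()) {
  m <- regmatches(label, regexec("^(\\*[0-9]+)?\\s?([TC][GA])$", label))[[1]]
  if (length(m) == 0) stop("unrecognized haplotype label: ", label)
  star <- if (m[2] == "") "*1" else m[2]
  cyp2c <- m[3]
  alleles <- panel$ref
  sites <- cyp2c_sites(panel)
  i1 <- match(sites$rsid[1], panel$rsid)
  i2 <- match(sites$rsid[2], panel$rsid)
  alleles[i1] <- substr(cyp2c, 1, 1)
  alleles[i2] <- substr(cyp2c, 2, 2)
  if (star != "*1") {
    def <- star_defs[star_defs$star_tag == star, , drop = FALSE]
    if (nrow(def) != 1) stop("star allele not in definition table: ", star)
    j <- match(def$rsid, panel$rsid)
    if (is.na(j)) stop("panel lacks the defining site of ", star, " (", def$rsid, ")")
    alleles[j] <- def$variant_allele
  }
  ok1 <- alleles[i1] %in% c(panel$ref[i1], panel$alt[i1])
  ok2 <- alleles[i2] %in% c(panel$ref[i2], panel$alt[i2])
  if (!ok1 || !ok2) stop("label alleles incompatible with panel: ", label)
  paste(alleles, collapse = "")
}
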