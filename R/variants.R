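#' Construct a variant table
#'
#' Variants are biallelic SNPs held as rows of a tibble with 1-based
#' positions. A variant must carry either an rsid or a (chrom, pos) pair;
#' rows with neither are rejected.
#'
#' @param rsid Character vector of dbSNP identifiers (NA allowed when
#'   chrom/pos are present).
#' @param chrom Chromosome names.
#' @param pos 1-based base-pair positions.
#' @param ref_allele,alt_allele Single-base allele strings; must differ.
#' @param locus_label Gene or locus label (e.g. "CD55").
#' @param region_class One of `region_classes()`; defaults to "unknown".
#' @return A tibble with one row per variant and columns `rsid`, `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `locus_label`, `region_class`.
#' @examples
#' variant_table("rs3138142", "12", 56115584, "C", "T", locus_label = "RDH5")
#' @export
variant_table <- function(rsid, chrom, pos, ref_allele = "A", alt_allele = "G",
                          locus_label = NA_character_,
                          region_class = "unknown") {
  v <- tibble(
    rsid = as.character(rsid), chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    locus_label = as.character(locus_label),
    region_class = as.character(region_class)
  )
  validate_variants(v)
}

#' Recognised variant region classes
#' @return Character vector of allowed `region_class` values.
#' @export
region_classes <- function() {
  c("intergenic", "intronic", "exon_synonymous", "exon_nonsynonymous",
    "utr5", "utr3", "unknown")
}

validate_variants <- function(v) {
  stopifnot(is.data.frame(v))
  no_id <- (is.na(v$rsid) | v$rsid == "") & (is.na(v$chrom) | is.na(v$pos))
  if (any(no_id)) {
    stop("variant rows without an rsid and without (chrom, pos): ",
         paste(which(no_id), collapse = ", "))
  }
  if (any(!is.na(v$pos) & v$pos < 1L)) stop("variant positions must be >= 1")
  same <- !is.na(v$ref_allele) & !is.na(v$alt_allele) &
    v$ref_allele == v$alt_allele
  if (any(same)) {
    stop("ref and alt alleles identical for rows: ",
         paste(which(same), collapse = ", "))
  }
  bad_rc <- !v$region_class %in% region_classes()
  if (any(bad_rc)) {
    stop("unknown region_class: ",
         paste(unique(v$region_class[bad_rc]), collapse = ", "))
  }
  v
}

# deficient = no usable identifier: missing/empty, or a bare position
# label ("chr8:60178580") in place of an rsid
is_deficient_id <- function(x) {
  is.na(x) | x == "" | grepl("^(chr)?[0-9XYMT]+:[0-9]+$", x,
                             ignore.case = TRUE)
}

#' Read a study's index-SNP table
#'
#' Reads a TSV of genome-wide significant SNPs. Required columns: `rsid`,
#' `chrom`, `pos`, `pvalue`; optional: `locus`, `study`. Rows whose
#' identifier is not a proper rsid (e.g. a raw "chr8:60178580" position
#' label) are returned with `deficient = TRUE` rather than dropped, so the
#' selection stage can count them explicitly.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param study_label Study label attached to every row when the file has
#'   no `study` column.
#' @return Tibble with columns `rsid`, `chrom`, `pos`, `gwas_pvalue`,
#'   `locus_label`, `study_label`, `deficient`.
#' @export
read_index_snps <- function(path, study_label = NA_character_) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("rsid", "chrom", "pos", "pvalue")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("index-SNP file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(tibble(rsid = character(), chrom = character(), pos = integer(),
                  gwas_pvalue = double(), locus_label = character(),
                  study_label = character(), deficient = logical()))
  }
  p <- suppressWarnings(as.numeric(raw$pvalue))
  bad_p <- which(is.na(p) & !is.na(raw$pvalue))
  if (length(bad_p) > 0) {
    stop("unparsable p-value in ", path, " at data line(s): ",
         paste(bad_p, collapse = ", "))
  }
  if (any(!is.na(p) & (p <= 0 | p > 1))) {
    stop("p-values must lie in (0, 1] in ", path)
  }
  tibble(
    rsid = raw$rsid,
    chrom = as.character(raw$chrom),
    pos = suppressWarnings(as.integer(raw$pos)),
    gwas_pvalue = p,
    locus_label = if ("locus" %in% names(raw)) raw$locus else NA_character_,
    study_label = if ("study" %in% names(raw)) raw$study else study_label,
    deficient = is_deficient_id(raw$rsid)
  )
}
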