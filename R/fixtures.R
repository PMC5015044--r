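re_extdata <- function(file) {
  path <- system.file("extdata", file, package = "proxyreg")
  if (path == "") stop("bundled fixture not found: ", file)
  path
}

#' Load the bundled refractive-error GWAS case study
#'
#' The package ships a desk-scale case study from a refractive-error
#' GWAS follow-up: the published annotation table of the 36 category-1
#' variants, their LD/category report, the full category distribution
#' over 868 queried variants, the per-locus proxy totals, and two
#' synthetic study index-SNP tables. In the index tables the handful of
#' index SNPs that reached category 1 carry their real rsids and
#' positions; the remaining entries are synthetic placeholders (rsids
#' `rs91.../rs92...`) standing in for index SNPs whose identities the
#' case study does not enumerate, arranged to reproduce its selection
#' arithmetic: 21 + 22 study entries sharing one rsid and containing two
#' deficient (rsid-less) entries, leaving 40 after selection.
#'
#' Shape checks run at load time; a mismatch signals fixture corruption.
#'
#' @return List with elements `annotations` (36 rows), `ld_categories`
#'   (36 rows), `distribution` (counts per label, 868 total),
#'   `locus_proxy_counts`, and `index_studies` (list of two index-SNP
#'   tibbles as from [read_index_snps()]).
#' @export
load_case_study <- function() {
  ann <- readr::read_tsv(re_extdata("re_annotations.tsv"),
                         col_types = readr::cols(.default = "c",
                                                 pos = "i", is_index = "i"),
                         progress = FALSE)
  ld <- readr::read_tsv(re_extdata("re_ld_categories.tsv"),
                        col_types = readr::cols(.default = "c",
                                                r2_bin = "d", is_index = "i"),
                        progress = FALSE)
  dist <- readr::read_tsv(re_extdata("re_category_distribution.tsv"),
                          col_types = readr::cols(.default = "c",
                                                  count = "i"),
                          progress = FALSE)
  lpc <- readr::read_tsv(re_extdata("re_locus_proxy_counts.tsv"),
                         col_types = "ci", progress = FALSE)
  cream <- read_index_snps(re_extdata("re_index_cream_synthetic.tsv"))
  andme <- read_index_snps(re_extdata("re_index_23andme_synthetic.tsv"))
  if (nrow(ann) != 36) stop("fixture corruption: annotations must have 36 rows")
  if (nrow(ld) != 36) stop("fixture corruption: LD/category table must have 36 rows")
  if (!setequal(dist$label, category_levels())) {
    stop("fixture corruption: distribution labels do not match the scheme")
  }
  if (sum(dist$count) != 868) {
    stop("fixture corruption: distribution must total 868 variants")
  }
  if (nrow(cream) != 21 || nrow(andme) != 22) {
    stop("fixture corruption: index studies must have 21 and 22 entries")
  }
  if (!all(ld$r2_bin %in% c(0.8, 0.9, 1.0))) {
    stop("fixture corruption: r2 bins must be 0.8/0.9/1.0")
  }
  list(annotations = ann, ld_categories = ld, distribution = dist,
       locus_proxy_counts = lpc, index_studies = list(CREAM = cream,
                                                      `23andMe` = andme))
}

#' Expand a category-distribution table into one row per variant
#'
#' Convenience for feeding count summaries back through the scoring
#' filters: each label contributes `count` rows ("ND" rows are dropped,
#' they represent variants with no score).
#'
#' @param dist Tibble with `label` and `count` columns.
#' @return Tibble with `rsid` (synthetic ordinal ids) and `label`, one
#'   row per scored variant.
#' @export
expand_distribution <- function(dist) {
  scored <- dist[dist$label != "ND", , drop = FALSE]
  tibble(
    rsid = paste0("v", seq_len(sum(scored$count))),
    label = rep(scored$label, scored$count)
  )
}
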