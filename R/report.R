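#' Floor an r-squared value into the reporting bins
#'
#' Report tables print r^2 binned at the query thresholds rather than the
#' exact value: 1.0 for complete LD, 0.9 for r^2 in \[0.9, 1), otherwise
#' 0.8 (proxies below 0.8 never reach the reports).
#'
#' @param r2 Numeric vector of r^2 values in \[0, 1\].
#' @return Numeric vector with values in {0.8, 0.9, 1.0}.
#' @export
bin_r2 <- function(r2) {
  ifelse(r2 >= 1 - 1e-12, 1.0, ifelse(r2 >= 0.9, 0.9, 0.8))
}

#' Distribution of variants over the category scheme
#'
#' @param scored Tibble with a `label` column; one row per scored variant.
#' @param total_queried Total number of variants queried (>= nrow(scored));
#'   the difference is added to the "ND" count.
#' @return List of class `category_distribution` with `counts` (named
#'   integer vector over all labels, ND last) and `total_queried`. Counts
#'   always sum to `total_queried`.
#' @export
category_distribution <- function(scored, total_queried = nrow(scored)) {
  if (total_queried < nrow(scored)) {
    stop("total_queried (", total_queried, ") smaller than the number of ",
         "scored variants (", nrow(scored), ")")
  }
  counts <- setNames(integer(length(category_levels())), category_levels())
  if (nrow(scored) > 0) {
    bad <- setdiff(unique(scored$label), category_levels())
    if (length(bad) > 0) stop("unknown labels: ", paste(bad, collapse = ", "))
    tab <- table(scored$label)
    counts[names(tab)] <- as.integer(tab)
  }
  counts[["ND"]] <- counts[["ND"]] + (total_queried - nrow(scored))
  structure(list(counts = counts, total_queried = as.integer(total_queried)),
            class = "category_distribution")
}

#' @export
print.category_distribution <- function(x, ...) {
  cat("<category_distribution> ", x$total_queried, " variants queried, ",
      sum(x$counts) - x$counts[["ND"]], " scored\n", sep = "")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' LD / category score report (index SNP vs functional proxies)
#'
#' One row per scored proxy: its index SNP, the r^2 bin linking the two,
#' and the proxy's category label. Rows are grouped by index SNP with the
#' index's own self-row (proxy == index) first, then by descending r^2 bin
#' and proxy rsid.
#'
#' @param proxies Proxy-record tibble (from [expand_proxies()] /
#'   [merge_proxy_sets()]); may carry a `locus` column.
#' @param scored Tibble with `rsid` and `label` for every variant to
#'   report. Every scored variant must have a proxy record.
#' @return Tibble: `index_rsid`, `proxy_rsid`, `r2_bin`, `label`,
#'   `is_index`, plus `locus` when available.
#' @export
ld_score_table <- function(proxies, scored) {
  orphans <- setdiff(scored$rsid, proxies$proxy_rsid)
  if (length(orphans) > 0) {
    stop("scored variant(s) without a proxy record: ",
         paste(orphans, collapse = ", "))
  }
  out <- proxies %>%
    filter(proxy_rsid %in% scored$rsid) %>%
    left_join(scored[, c("rsid", "label")],
              by = c(proxy_rsid = "rsid")) %>%
    mutate(r2_bin = bin_r2(r2), is_index = proxy_rsid == index_rsid)
  keep <- c("index_rsid", "proxy_rsid", "r2_bin", "label", "is_index",
            intersect("locus", names(out)))
  out %>%
    mutate(self_first = !is_index) %>%
    arrange(index_rsid, self_first, dplyr::desc(r2_bin), proxy_rsid) %>%
    select(dplyr::all_of(keep))
}

#' Per-locus summary of regulatory potential
#'
#' Counts, per GWAS locus, the category-1 variants, the index SNPs, and
#' how many index SNPs themselves scored in category 1. Loci carrying two
#' index SNPs are counted once under their shared label. Invariant under
#' row permutation of the report.
#'
#' @param report A Table-shaped report from [ld_score_table()] with a
#'   `locus` column.
#' @param index_snps Optional index-SNP tibble (with `rsid`,
#'   `locus_label`); defaults to the report's `is_index` rows.
#' @param proxy_counts Optional tibble (`locus`, `n_proxies`) giving the
#'   number of proxies investigated per locus (the report itself only
#'   holds the scored ones).
#' @return Tibble: `locus`, `n_category1`, `n_proxies_investigated`,
#'   `index_rsids`, `n_index_in_category1`.
#' @export
locus_summary <- function(report, index_snps = NULL, proxy_counts = NULL) {
  if (!"locus" %in% names(report)) {
    stop("locus_summary needs a 'locus' column in the report")
  }
  index_by_locus <- report %>%
    distinct(locus, index_rsid) %>%
    group_by(locus) %>%
    summarise(index_rsids = paste(sort(unique(index_rsid)), collapse = ","),
              .groups = "drop")
  out <- report %>%
    group_by(locus) %>%
    summarise(
      n_category1 = sum(category_major(label) == 1, na.rm = TRUE),
      n_index_in_category1 = sum(is_index &
                                   category_major(label) == 1, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    left_join(index_by_locus, by = "locus")
  if (!is.null(proxy_counts)) {
    out <- left_join(out, rename(proxy_counts,
                                 n_proxies_investigated = "n_proxies"),
                     by = "locus")
    low <- !is.na(out$n_proxies_investigated) &
      out$n_category1 > out$n_proxies_investigated
    if (any(low)) {
      stop("locus with more category-1 variants than proxies investigated: ",
           paste(out$locus[low], collapse = ", "))
    }
  } else {
    out$n_proxies_investigated <- NA_integer_
  }
  arrange(select(out, locus, n_category1, n_proxies_investigated,
                 index_rsids, n_index_in_category1), locus)
}

# "scoring; secondary" cell rendering: scoring/both items first (both-source
# items starred), then "; " and the secondary-only items. Empty scoring set
# with secondary items renders as "-; ...".
render_source_cell <- function(names, sources, empty = "-") {
  stopifnot(length(names) == length(sources))
  keep <- !is.na(names) & names != ""
  names <- names[keep]; sources <- sources[keep]
  if (length(names) == 0) return(empty)
  prim <- names[sources %in% c("scoring", "both")]
  stars <- ifelse(sources[sources %in% c("scoring", "both")] == "both",
                  "*", "")
  sec <- names[sources == "secondary"]
  left <- if (length(prim) > 0) paste0(prim, stars, collapse = ", ") else "-"
  if (length(sec) > 0) paste0(left, "; ", paste(sec, collapse = ", "))
  else left
}

parse_source_cell <- function(cell, empty = "-") {
  if (is.na(cell) || cell == "" || cell == empty) {
    return(tibble(name = character(), source = character()))
  }
  halves <- strsplit(cell, ";\\s*")[[1]]
  split_items <- function(s) {
    s <- trimws(strsplit(s, ",\\s*")[[1]])
    s[s != "" & s != empty]
  }
  prim <- if (length(halves) >= 1) split_items(halves[1]) else character()
  sec <- if (length(halves) >= 2) split_items(paste(halves[-1],
                                                    collapse = "; "))
         else character()
  bind_rows(
    tibble(name = sub("\\*$", "", prim),
           source = c("scoring", "both")[1L + grepl("\\*$", prim)]),
    tibble(name = sub("\\*$", "", sec),
           source = rep("secondary", length(sec)))
  )
}

#' Annotation report over merged evidence profiles
#'
#' One row per variant: presence marks (+/-) for histone marks, DNase
#' evidence and eQTL status, then the "motifs altered" and "protein bound"
#' name lists rendered with the two-source convention — scoring-source
#' items first (items present in both sources starred), a semicolon, then
#' secondary-only items.
#'
#' @param profiles List of merged `evidence_profile`s.
#' @param deltas Optional named list (by rsid) of [motif_delta()] tibbles;
#'   altered motifs are added to the motif column.
#' @return Tibble: `chrom`, `pos`, `rsid`, `allele`, `locus`,
#'   `region_class`, `histone_marked`, `dnase`, `eqtl`, `motifs_altered`,
#'   `protein_bound`.
#' @export
annotation_table <- function(profiles, deltas = NULL) {
  rows <- lapply(profiles, function(pr) {
    v <- pr$variant
    r <- pr$records
    of_kind <- function(k) r[r$kind == k, , drop = FALSE]
    motifs <- of_kind("motif_instance")
    if (!is.null(deltas) && !is.null(v$rsid) && v$rsid %in% names(deltas)) {
      d <- deltas[[v$rsid]]
      extra <- d$tf_name[d$altered & !d$tf_name %in% motifs$name]
      if (length(extra) > 0) {
        motifs <- bind_rows(motifs, tibble(name = extra, source = "scoring"))
      }
    }
    peaks <- of_kind("tf_peak")
    scoring_dnase <- of_kind("dnase_peak")
    tibble(
      chrom = v$chrom, pos = v$pos, rsid = v$rsid,
      allele = paste0(v$ref_allele, "/", v$alt_allele),
      locus = v$locus_label, region_class = v$region_class,
      histone_marked = if (nrow(of_kind("histone_mark")) > 0) "+" else "-",
      dnase = if (nrow(scoring_dnase) > 0) "+" else "-",
      eqtl = if (nrow(of_kind("eqtl")) > 0) "+" else "-",
      motifs_altered = render_source_cell(motifs$name, motifs$source),
      protein_bound = render_source_cell(peaks$name, peaks$source,
                                         empty = "")
    )
  })
  arrange(bind_rows(rows), chrom, pos)
}
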