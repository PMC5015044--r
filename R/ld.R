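#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes the classical two-locus LD summaries from haplotype counts:
#' D = p_AB - p_A p_B, Lewontin's D' = |D| / D_max, and
#' r^2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B)), where "A"/"B" denote the
#' alternate-allele indicators at the two sites. All three are invariant
#' under swapping the allele coding at either site (D and D' up to sign,
#' which is dropped), and r^2(x, x) = 1 for any polymorphic site.
#'
#' @param panel A [haplotype_panel()].
#' @param i,j Variant column indices (or rsids) of the two sites.
#' @return List with elements `d`, `d_prime`, `r2`.
#' @examples
#' p <- construct_pair_with_r2(0.85, 0.5, 0.5, 2000)
#' compute_pairwise_ld(p, 1, 2)$r2
#' @export
compute_pairwise_ld <- function(panel, i, j) {
  i <- resolve_variant_index(panel, i)
  j <- resolve_variant_index(panel, j)
  x <- panel$alleles[, i]
  y <- panel$alleles[, j]
  pa <- mean(x)
  pb <- mean(y)
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("LD undefined: monomorphic variant (index ",
         if (pa <= 0 || pa >= 1) i else j, ")")
  }
  pab <- mean(x == 1L & y == 1L)
  d <- pab - pa * pb
  d_max <- if (d >= 0) min(pa * (1 - pb), (1 - pa) * pb)
           else min(pa * pb, (1 - pa) * (1 - pb))
  d_prime <- if (d_max == 0) 0 else abs(d) / d_max
  r2 <- d^2 / (pa * (1 - pa) * pb * (1 - pb))
  list(d = d, d_prime = min(d_prime, 1), r2 = min(r2, 1))
}

resolve_variant_index <- function(panel, i) {
  if (is.character(i)) {
    idx <- match(i, panel$variants$rsid)
    if (is.na(idx)) {
      stop("variant ", i, " not found in panel ", panel$panel_label)
    }
    return(idx)
  }
  i <- as.integer(i)
  if (i < 1 || i > n_variants(panel)) stop("variant index out of range: ", i)
  i
}

#' Expand an index SNP to its LD proxy set within a panel
#'
#' Every polymorphic panel variant on the index SNP's chromosome within
#' `window_bp` whose r^2 with the index is at or above `r2_threshold`
#' becomes a proxy record; the index SNP always appears in its own proxy
#' set with r^2 = 1. Monomorphic variants are excluded with a warning
#' (their LD is undefined).
#'
#' @param panel A [haplotype_panel()].
#' @param index_rsid rsid of the index SNP; must be present and
#'   polymorphic in the panel.
#' @param r2_threshold Inclusion threshold, applied as r^2 >= threshold.
#' @param window_bp Maximum base-pair distance from the index SNP.
#' @return Tibble of proxy records: `index_rsid`, `proxy_rsid`, `chrom`,
#'   `pos`, `r2`, `d_prime`, `distance_bp`, `panel`.
#' @export
expand_proxies <- function(panel, index_rsid, r2_threshold = 0.8,
                           window_bp = 500000L) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  idx <- resolve_variant_index(panel, index_rsid)
  if (panel$monomorphic[idx]) {
    stop("index SNP ", index_rsid, " is monomorphic in panel ",
         panel$panel_label)
  }
  v <- panel$variants
  cand <- which(v$chrom == v$chrom[idx] &
                abs(v$pos - v$pos[idx]) <= window_bp)
  mono <- cand[panel$monomorphic[cand]]
  if (length(mono) > 0) {
    warning(length(mono), " monomorphic variant(s) excluded from proxy ",
            "search for ", index_rsid)
    cand <- setdiff(cand, mono)
  }
  rows <- lapply(cand, function(j) {
    ld <- compute_pairwise_ld(panel, idx, j)
    if (ld$r2 >= r2_threshold || j == idx) {
      tibble(index_rsid = v$rsid[idx], proxy_rsid = v$rsid[j],
             chrom = v$chrom[j], pos = v$pos[j], r2 = ld$r2,
             d_prime = ld$d_prime, distance_bp = abs(v$pos[j] - v$pos[idx]),
             panel = panel$panel_label)
    }
  })
  arrange(bind_rows(rows), chrom, pos)
}

#' Merge proxy sets from several panels
#'
#' Union keyed on (index_rsid, proxy_rsid). When panels disagree on a
#' pair's r^2 the record with the larger r^2 survives (so thresholding
#' after the merge is conservative-inclusive) and keeps its panel label.
#' Idempotent and order-insensitive up to the output sort.
#'
#' @param sets A list of proxy-record tibbles as from [expand_proxies()],
#'   or a single such tibble.
#' @param ... Further proxy-record tibbles when `sets` is a tibble.
#' @return Single proxy-record tibble sorted by (index_rsid, chrom, pos).
#' @export
merge_proxy_sets <- function(sets, ...) {
  if (is.data.frame(sets)) sets <- c(list(sets), list(...))
  all <- bind_rows(sets)
  if (nrow(all) == 0) return(all)
  all %>%
    group_by(index_rsid, proxy_rsid) %>%
    slice_max(r2, n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    arrange(index_rsid, chrom, pos)
}
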