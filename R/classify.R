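#' Category labels in ordinal order
#'
#' The ordered evidence categories: 1a carries the strongest regulatory
#' evidence, 6 the weakest, and "ND" (no data) is a sentinel for variants
#' with no evidence record at all. Subletters rank within a major numeral,
#' never across.
#'
#' @return Character vector of the 15 labels in ordinal order (1a best).
#' @export
category_levels <- function() {
  c("1a", "1b", "1c", "1d", "1e", "1f", "2a", "2b", "2c",
    "3a", "3b", "4", "5", "6", "ND")
}

#' Major numeral of a category label
#' @param label Character vector of labels from `category_levels()`.
#' @return Integer vector; NA for "ND" (never comparable to 1-6).
#' @export
category_major <- function(label) {
  out <- rep(NA_integer_, length(label))
  num <- grepl("^[1-6]", label)
  out[num] <- as.integer(substr(label[num], 1, 1))
  out
}

#' Ordinal rank of a category label (1a = 1, ND = 15)
#' @param label Character vector of labels.
#' @return Integer rank.
#' @export
category_ordinal <- function(label) {
  match(label, category_levels())
}

flag_names <- function() {
  c("has_eqtl", "has_tf_binding", "has_motif_any", "has_motif_matched",
    "has_footprint", "has_footprint_matched", "has_dnase_peak",
    "has_motif_hit")
}

#' Boolean evidence summary of a variant
#'
#' @param has_eqtl Variant is an eQTL for some gene.
#' @param has_tf_binding At least one TF ChIP-seq peak covers the variant.
#' @param has_motif_any A motif instance lies at the variant within a TF
#'   peak context ("any motif").
#' @param has_motif_matched The motif's TF is one of the bound TFs
#'   ("matched TF motif").
#' @param has_footprint A DNase footprint covers the variant.
#' @param has_footprint_matched The footprint's motif TF is a bound TF.
#' @param has_dnase_peak A DNase hypersensitivity peak covers the variant.
#' @param has_motif_hit Any motif instance at all covers the variant.
#' @return Named logical vector of class `evidence_flags`. Construction
#'   enforces the implications matched motif => any motif => motif hit and
#'   matched footprint => footprint.
#' @export
evidence_flags <- function(has_eqtl = FALSE, has_tf_binding = FALSE,
                           has_motif_any = FALSE, has_motif_matched = FALSE,
                           has_footprint = FALSE,
                           has_footprint_matched = FALSE,
                           has_dnase_peak = FALSE, has_motif_hit = FALSE) {
  f <- c(has_eqtl = has_eqtl, has_tf_binding = has_tf_binding,
         has_motif_any = has_motif_any, has_motif_matched = has_motif_matched,
         has_footprint = has_footprint,
         has_footprint_matched = has_footprint_matched,
         has_dnase_peak = has_dnase_peak, has_motif_hit = has_motif_hit)
  stopifnot(is.logical(f), !anyNA(f))
  check_flag_invariants(f)
  structure(f, class = c("evidence_flags", "logical"))
}

check_flag_invariants <- function(f) {
  if (f[["has_motif_matched"]] && !f[["has_motif_any"]]) {
    stop("invalid flags: matched motif without any-motif")
  }
  if (f[["has_motif_any"]] && !f[["has_motif_hit"]]) {
    stop("invalid flags: any-motif without a motif hit")
  }
  if (f[["has_footprint_matched"]] && !f[["has_footprint"]]) {
    stop("invalid flags: matched footprint without a footprint")
  }
  invisible(f)
}

#' Derive evidence flags from a merged evidence profile
#'
#' Only records from the scoring source (tags "scoring" or "both") are
#' considered; secondary-only annotations never contribute to flags.
#' A motif instance counts as "any motif" when the variant also carries a
#' scoring TF peak (the peak provides the binding context); it counts as
#' "matched" when its TF is one of the bound TFs after alias
#' canonicalization, and likewise for footprints. Histone marks never
#' enter the flags.
#'
#' @param profile An `evidence_profile` (merged or scoring-only).
#' @param motif_results Optional tibble of [motif_delta()] rows; motifs
#'   with `altered = TRUE` add motif evidence beyond the instance tracks.
#' @param alias_map Optional alias map for TF-identity matching.
#' @return An [evidence_flags()] vector.
#' @export
derive_flags <- function(profile, motif_results = NULL, alias_map = NULL) {
  r <- profile$records
  scoring <- r[r$source %in% c("scoring", "both"), , drop = FALSE]
  of_kind <- function(k) scoring[scoring$kind == k, , drop = FALSE]
  bound_tfs <- unique(of_kind("tf_peak")$name)
  motif_tfs <- unique(of_kind("motif_instance")$name)
  if (!is.null(motif_results) && nrow(motif_results) > 0) {
    motif_tfs <- unique(c(motif_tfs,
                          motif_results$tf_name[motif_results$altered]))
  }
  motif_tfs <- motif_tfs[!is.na(motif_tfs)]
  fp_tfs <- unique(of_kind("dnase_footprint")$name)
  has_tf <- length(bound_tfs) > 0
  has_hit <- length(motif_tfs) > 0
  matched_motif <- any(vapply(motif_tfs, is_matched, logical(1),
                              bound_tfs = bound_tfs, alias_map = alias_map))
  has_fp <- nrow(of_kind("dnase_footprint")) > 0
  matched_fp <- any(vapply(fp_tfs[!is.na(fp_tfs)], is_matched, logical(1),
                           bound_tfs = bound_tfs, alias_map = alias_map))
  evidence_flags(
    has_eqtl = nrow(of_kind("eqtl")) > 0,
    has_tf_binding = has_tf,
    has_motif_any = has_hit && has_tf,
    has_motif_matched = matched_motif,
    has_footprint = has_fp,
    has_footprint_matched = matched_fp,
    has_dnase_peak = nrow(of_kind("dnase_peak")) > 0,
    has_motif_hit = has_hit
  )
}

#' Classify evidence flags into a category label
#'
#' The decision table, applied first-match in ordinal order:
#' \describe{
#'   \item{1a}{eQTL + TF binding + matched TF motif + matched DNase
#'     footprint + DNase peak}
#'   \item{1b}{eQTL + TF binding + any motif + DNase footprint + DNase peak}
#'   \item{1c}{eQTL + TF binding + matched TF motif + DNase peak}
#'   \item{1d}{eQTL + TF binding + any motif + DNase peak}
#'   \item{1e}{eQTL + TF binding + matched TF motif}
#'   \item{1f}{eQTL + (TF binding or DNase peak)}
#'   \item{2a}{TF binding + matched TF motif + matched DNase footprint +
#'     DNase peak}
#'   \item{2b}{TF binding + any motif + DNase footprint + DNase peak}
#'   \item{2c}{TF binding + matched TF motif + DNase peak}
#'   \item{3a}{TF binding + any motif + DNase peak}
#'   \item{3b}{TF binding + matched TF motif}
#'   \item{4}{TF binding + DNase peak}
#'   \item{5}{TF binding or DNase peak}
#'   \item{6}{motif hit}
#'   \item{ND}{none of the above}
#' }
#' Both "TF binding/DNase peak" readings (1f, 5) are inclusive OR.
#'
#' @param flags An [evidence_flags()] vector (invariant-violating flags
#'   are an error, never silently classified).
#' @return A single label from `category_levels()`.
#' @export
classify <- function(flags) {
  f <- as.list(flags)
  check_flag_invariants(flags)
  with(f, {
    if (has_eqtl && has_tf_binding && has_motif_matched &&
        has_footprint_matched && has_dnase_peak) return("1a")
    if (has_eqtl && has_tf_binding && has_motif_any && has_footprint &&
        has_dnase_peak) return("1b")
    if (has_eqtl && has_tf_binding && has_motif_matched && has_dnase_peak)
      return("1c")
    if (has_eqtl && has_tf_binding && has_motif_any && has_dnase_peak)
      return("1d")
    if (has_eqtl && has_tf_binding && has_motif_matched) return("1e")
    if (has_eqtl && (has_tf_binding || has_dnase_peak)) return("1f")
    if (has_tf_binding && has_motif_matched && has_footprint_matched &&
        has_dnase_peak) return("2a")
    if (has_tf_binding && has_motif_any && has_footprint && has_dnase_peak)
      return("2b")
    if (has_tf_binding && has_motif_matched && has_dnase_peak) return("2c")
    if (has_tf_binding && has_motif_any && has_dnase_peak) return("3a")
    if (has_tf_binding && has_motif_matched) return("3b")
    if (has_tf_binding && has_dnase_peak) return("4")
    if (has_tf_binding || has_dnase_peak) return("5")
    if (has_motif_hit) return("6")
    "ND"
  })
}

#' Filter scored variants by major category numeral
#'
#' @param scored Tibble with at least a `label` column (values from
#'   `category_levels()`).
#' @param max_major Keep rows whose major numeral is <= this value. "ND"
#'   rows never pass.
#' @return The filtered tibble, input order preserved.
#' @export
filter_by_score <- function(scored, max_major) {
  maj <- category_major(scored$label)
  scored[!is.na(maj) & maj <= max_major, , drop = FALSE]
}
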