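#' Build a position-queryable index over annotation tracks
#'
#' Each track kind becomes a `GRanges` (converted from the tracks' 0-based
#' half-open coordinates to the 1-based closed convention GRanges uses),
#' so that a point query at 1-based position p returns exactly the
#' intervals with start <= p - 1 < end.
#'
#' @param tracks One interval tibble (as from [read_track()]) or a list of
#'   them; kinds may be mixed, they are separated internally.
#' @return Object of class `evidence_index`.
#' @export
build_interval_index <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  all <- bind_rows(tracks)
  if (nrow(all) == 0 || !"kind" %in% names(all)) {
    all <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), cell_type = character(),
                  pwm_id = character(), strand = character(),
                  kind = character(), source = character())
  }
  by_kind <- lapply(setNames(nm = track_kinds()), function(k) {
    tk <- filter(all, kind == k)
    if (nrow(tk) == 0) return(NULL)
    gr <- GenomicRanges::GRanges(
      seqnames = tk$chrom,
      ranges = IRanges::IRanges(start = tk$start + 1L, end = tk$end)
    )
    S4Vectors::mcols(gr) <- tk[, c("name", "cell_type", "pwm_id", "strand",
                                   "kind", "source")]
    gr
  })
  structure(list(by_kind = by_kind), class = "evidence_index")
}

#' Query an evidence index at a single genomic position
#'
#' @param index An `evidence_index` from [build_interval_index()].
#' @param chrom Chromosome name.
#' @param pos 1-based position.
#' @return Tibble of overlapping records (all kinds) with interval
#'   coordinates restored to 0-based half-open.
#' @export
query_evidence_index <- function(index, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- lapply(index$by_kind, function(gr) {
    if (is.null(gr)) return(NULL)
    ov <- gr[S4Vectors::subjectHits(GenomicRanges::findOverlaps(q, gr))]
    if (length(ov) == 0) return(NULL)
    cbind(
      tibble(chrom = as.character(GenomicRanges::seqnames(ov)),
             start = GenomicRanges::start(ov) - 1L,
             end = GenomicRanges::end(ov)),
      as_tibble(S4Vectors::mcols(ov))
    )
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), cell_type = character(),
                  pwm_id = character(), strand = character(),
                  kind = character(), source = character())
  }
  as_tibble(out)
}

#' Assemble the evidence profile of one variant
#'
#' Collects every annotation-track interval overlapping the variant's
#' position plus every eQTL association for the variant (matched by rsid
#' first, then by chrom/pos). Evidence is collapsed across cell types:
#' cell-type labels are retained for reporting but any single overlapping
#' record of a kind is enough to establish that kind of evidence.
#'
#' @param variant One-row variant tibble (see [variant_table()]).
#' @param index An `evidence_index`.
#' @param eqtls eQTL tibble from [read_eqtl()] (may be empty or NULL).
#' @return Object of class `evidence_profile`: list with `variant`,
#'   `records` (interval + eqtl records with `kind` and `source`), and
#'   `eqtl_targets`.
#' @export
collect_evidence <- function(variant, index, eqtls = NULL) {
  stopifnot(nrow(variant) == 1)
  recs <- query_evidence_index(index, variant$chrom, variant$pos)
  if (!is.null(eqtls) && nrow(eqtls) > 0) {
    hit <- if (!is.na(variant$rsid) && variant$rsid %in% eqtls$rsid) {
      filter(eqtls, rsid == variant$rsid)
    } else {
      filter(eqtls, chrom == variant$chrom, pos == variant$pos)
    }
    if (nrow(hit) > 0) {
      recs <- bind_rows(recs, tibble(
        chrom = hit$chrom, start = NA_integer_, end = NA_integer_,
        name = hit$target_gene, cell_type = hit$tissue,
        pwm_id = NA_character_, strand = NA_character_,
        kind = "eqtl", source = hit$source
      ))
    }
  }
  new_evidence_profile(variant, recs)
}

new_evidence_profile <- function(variant, records) {
  structure(
    list(variant = variant, records = as_tibble(records),
         eqtl_targets = unique(records$name[records$kind == "eqtl"])),
    class = "evidence_profile"
  )
}

#' @export
print.evidence_profile <- function(x, ...) {
  cat("<evidence_profile> ", x$variant$rsid, " (", x$variant$chrom, ":",
      x$variant$pos, "): ", nrow(x$records), " record(s)\n", sep = "")
  if (nrow(x$records) > 0) {
    print(table(x$records$kind, x$records$source))
  }
  invisible(x)
}

#' Merge a scoring-source profile with a secondary-source profile
#'
#' Implements the two-database annotation convention: records present in
#' both sources (same kind and same TF/mark/gene name) are kept once and
#' tagged `"both"` (rendered with an asterisk in reports); records only in
#' the secondary source are tagged `"secondary"` and never enter the
#' scoring flags. Scoring records are never removed and secondary-only
#' records are never promoted.
#'
#' @param primary_profile,secondary_profile `evidence_profile`s for the
#'   same variant, from the scoring and the secondary annotation source.
#' @return Merged `evidence_profile`.
#' @export
merge_annotation_sources <- function(primary_profile, secondary_profile) {
  vp <- primary_profile$variant
  vs <- secondary_profile$variant
  same <- identical(vp$rsid, vs$rsid) ||
    (identical(vp$chrom, vs$chrom) && identical(vp$pos, vs$pos))
  if (!same) {
    stop("cannot merge annotation sources for different variants: ",
         vp$rsid, " vs ", vs$rsid)
  }
  prim <- primary_profile$records
  sec <- secondary_profile$records
  key <- function(df) paste(df$kind, toupper(ifelse(is.na(df$name), "",
                                                    df$name)))
  if (nrow(prim) > 0) {
    prim$source <- ifelse(key(prim) %in% key(sec), "both", "scoring")
  }
  if (nrow(sec) > 0) {
    sec <- sec[!(key(sec) %in% key(prim)), , drop = FALSE]
    if (nrow(sec) > 0) sec$source <- "secondary"
  }
  new_evidence_profile(vp, bind_rows(prim, sec))
}
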