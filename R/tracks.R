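track_kinds <- function() {
  c("tf_peak", "dnase_peak", "dnase_footprint", "motif_instance",
    "histone_mark")
}

# per-kind extra columns expected after chrom/start/end in track TSVs
track_schema <- list(
  tf_peak = c("tf_name", "cell_type"),
  dnase_peak = c("cell_type"),
  dnase_footprint = c("motif_tf", "cell_type"),
  motif_instance = c("tf_name", "pwm_id", "strand"),
  histone_mark = c("mark_name", "cell_type")
)

#' Read an annotation track of genomic intervals
#'
#' Tracks are BED-derived TSVs: `chrom`, `start`, `end` (0-based
#' half-open) followed by track-type-specific metadata columns —
#' `tf_name`/`cell_type` for ChIP-seq peaks, `cell_type` for DNase peaks,
#' `motif_tf`/`cell_type` for DNase footprints, `tf_name`/`pwm_id`/`strand`
#' for motif instances, `mark_name`/`cell_type` for histone marks. Strand
#' is retained only for motif instances.
#'
#' @param path TSV path with a header row.
#' @param track_type One of `track_kinds()`.
#' @param source Evidence source tag, "scoring" or "secondary".
#' @return Tibble of intervals sorted by (chrom, start) with columns
#'   `chrom`, `start`, `end`, `name`, `cell_type`, `pwm_id`, `strand`,
#'   `kind`, `source`. `name` holds the TF, footprint-motif TF, or mark
#'   name depending on the kind.
#' @export
read_track <- function(path, track_type, source = "scoring") {
  track_type <- match.arg(track_type, track_kinds())
  source <- match.arg(source, c("scoring", "secondary"))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("chrom", "start", "end", track_schema[[track_type]])
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("track file ", path, " (", track_type,
         ") is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  start <- as.integer(raw$start)
  end <- as.integer(raw$end)
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad) > 0) {
    stop("invalid interval (need 0 <= start < end) in ", path,
         " at data line(s): ", paste(bad, collapse = ", "))
  }
  name_col <- switch(track_type,
    tf_peak = raw$tf_name, dnase_peak = rep(NA_character_, nrow(raw)),
    dnase_footprint = raw$motif_tf, motif_instance = raw$tf_name,
    histone_mark = raw$mark_name)
  out <- tibble(
    chrom = raw$chrom, start = start, end = end,
    name = name_col,
    cell_type = if ("cell_type" %in% names(raw)) raw$cell_type
                else NA_character_,
    pwm_id = if ("pwm_id" %in% names(raw)) raw$pwm_id else NA_character_,
    strand = if (track_type == "motif_instance" && "strand" %in% names(raw))
               raw$strand else NA_character_,
    kind = track_type, source = source
  )
  arrange(out, chrom, start, end)
}

#' Write an annotation track to TSV
#'
#' Inverse of [read_track()]: writes the kind-specific columns of an
#' interval tibble (as produced by [read_track()] or [plant_evidence()]).
#'
#' @param track Interval tibble with a single `kind`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  kind <- unique(track$kind)
  if (length(kind) != 1) stop("write_track expects a single track kind")
  extra <- track_schema[[kind]]
  out <- track[, c("chrom", "start", "end")]
  for (col in extra) {
    out[[col]] <- switch(col,
      tf_name = track$name, motif_tf = track$name, mark_name = track$name,
      cell_type = track$cell_type, pwm_id = track$pwm_id,
      strand = track$strand)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an eQTL association table
#'
#' eQTL evidence is keyed by variant (rsid, with positional fallback), not
#' by interval. Expected columns: `rsid`, `chrom`, `pos`, `target_gene`;
#' optional `tissue`, `statistic`.
#'
#' @param path TSV path.
#' @param source Evidence source tag, "scoring" or "secondary".
#' @return Tibble with columns `rsid`, `chrom`, `pos`, `target_gene`,
#'   `tissue`, `statistic`, `source`.
#' @export
read_eqtl <- function(path, source = "scoring") {
  source <- match.arg(source, c("scoring", "secondary"))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("rsid", "chrom", "pos", "target_gene")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("eQTL file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tibble(
    rsid = raw$rsid, chrom = raw$chrom, pos = as.integer(raw$pos),
    target_gene = raw$target_gene,
    tissue = if ("tissue" %in% names(raw)) raw$tissue else NA_character_,
    statistic = if ("statistic" %in% names(raw))
      suppressWarnings(as.numeric(raw$statistic)) else NA_real_,
    source = source
  )
}

#' Does a 1-based variant position fall in a 0-based half-open interval?
#'
#' The single place where the two coordinate conventions meet: a variant
#' at 1-based position p overlaps \[start, end) iff start <= p - 1 < end.
#'
#' @param pos 1-based position(s).
#' @param start,end 0-based half-open interval bounds.
#' @return Logical vector.
#' @export
pos_in_interval <- function(pos, start, end) {
  start <= pos - 1L & pos - 1L < end
}

#' Write a report table as TSV
#'
#' Deterministic output: the column order of `table` is preserved and rows
#' are written as given (report builders sort their rows themselves); an
#' empty table yields a header-only file.
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE, na = "")
  invisible(path)
}
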