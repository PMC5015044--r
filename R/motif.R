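#' Construct a position weight matrix
#'
#' @param tf_name Transcription factor the motif belongs to.
#' @param probs L x 4 matrix of base probabilities, columns in A, C, G, T
#'   order; each row must sum to 1 (before the pseudocount is applied).
#' @param pseudocount Probability mass added to every cell before
#'   renormalization; keeps log-odds finite when a cell is 0.
#' @return Object of class `pwm`.
#' @export
pwm <- function(tf_name, probs, pseudocount = 0.01) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("PWM needs 4 columns (A, C, G, T)")
  if (nrow(probs) < 4) stop("PWM must have length >= 4, got ", nrow(probs))
  if (any(probs < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("PWM rows must each sum to 1")
  }
  probs <- probs + pseudocount
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, probs = probs,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf_name, ", length ", nrow(x$probs), "\n", sep = "")
  invisible(x)
}

#' Read position weight matrices from a text file
#'
#' Format: a header line `>tf_name`, then L whitespace-separated rows of 4
#' probabilities (A, C, G, T order). Multiple matrices per file allowed.
#'
#' @param path PWM file path.
#' @param pseudocount Passed to [pwm()].
#' @return Named list of `pwm` objects (names are the TF names).
#' @export
read_pwm <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != ""]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>tf_name' header in PWM file ", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- lapply(seq_along(heads), function(k) {
    name <- sub("^>\\s*", "", lines[heads[k]])
    body <- lines[(heads[k] + 1L):(bounds[k + 1L] - 1L)]
    rows <- lapply(strsplit(body, "\\s+"), as.numeric)
    if (any(vapply(rows, length, 1L) != 4)) {
      stop("PWM ", name, " in ", path, ": every row needs 4 values")
    }
    pwm(name, do.call(rbind, rows), pseudocount = pseudocount)
  })
  setNames(out, vapply(out, function(p) p$tf_name, character(1)))
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp <- function(seq) {
  paste(rev(DNA_COMPLEMENT[strsplit(seq, "")[[1]]]), collapse = "")
}

seq_to_codes <- function(seq) {
  codes <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(codes)) stop("sequence contains non-ACGT characters")
  codes
}

score_window <- function(pwm, codes, background) {
  sum(log2(pwm$probs[cbind(seq_along(codes), codes)] / background[codes]))
}

#' Best log-odds PWM score over a sequence
#'
#' Scans every offset on both strands and returns the maximum log-odds
#' score sum(log2(p_base / bg_base)) in bits. Ties break to the smallest
#' offset, then the forward strand. Offsets are 1-based positions on the
#' forward sequence; a reverse-strand hit at offset o scores the reverse
#' complement of the forward window starting at o.
#'
#' @param pwm A [pwm()].
#' @param sequence ACGT string, at least as long as the motif.
#' @param background Length-4 base probabilities (A, C, G, T); default
#'   uniform.
#' @param offsets Optional subset of forward offsets to scan (used by
#'   [motif_delta()] to restrict to windows overlapping a variant).
#' @return List with `score` (bits), `offset`, `strand` ("+" or "-").
#' @export
pwm_best_logodds <- function(pwm, sequence, background = rep(0.25, 4),
                             offsets = NULL) {
  stopifnot(abs(sum(background) - 1) < 1e-6)
  L <- nrow(pwm$probs)
  fwd <- seq_to_codes(sequence)
  if (length(fwd) < L) stop("sequence shorter than motif")
  all_offsets <- seq_len(length(fwd) - L + 1L)
  if (!is.null(offsets)) {
    all_offsets <- intersect(all_offsets, offsets)
    if (length(all_offsets) == 0) stop("no scannable window at the given offsets")
  }
  best <- list(score = -Inf, offset = NA_integer_, strand = NA_character_)
  for (o in all_offsets) {
    win <- fwd[o:(o + L - 1L)]
    for (strand in c("+", "-")) {
      codes <- if (strand == "+") win else rev(5L - win)
      s <- score_window(pwm, codes, background)
      if (s > best$score + 1e-12) {
        best <- list(score = s, offset = o, strand = strand)
      }
    }
  }
  best
}

#' Allele-differential motif score for a variant
#'
#' Scores the motif on the reference and alternate versions of the
#' sequence context around the variant, restricting the scan to windows
#' that overlap the variant position, and flags the motif as altered when
#' the score difference exceeds the threshold in either direction.
#'
#' @param pwm A [pwm()].
#' @param context ACGT string centered on the variant (odd length); the
#'   central base must equal the variant's reference allele. Must extend
#'   at least L - 1 bases on each side of the variant.
#' @param variant One-row variant tibble.
#' @param threshold Bits of log-odds change at or above which the motif
#'   counts as altered.
#' @param background Base probabilities for the log-odds.
#' @return Tibble row: `pwm_id`, `tf_name`, `ref_score`, `alt_score`,
#'   `delta` (alt - ref, bits), `altered`.
#' @export
motif_delta <- function(pwm, context, variant, threshold = 1.0,
                        background = rep(0.25, 4)) {
  context <- toupper(context)
  n <- nchar(context)
  if (n %% 2 != 1) stop("context must have odd length (variant centered)")
  var_pos <- (n + 1L) %/% 2L
  L <- nrow(pwm$probs)
  if (var_pos - 1L < L - 1L || n - var_pos < L - 1L) {
    stop("context must cover at least ", L - 1, " bases each side of the variant")
  }
  if (substr(context, var_pos, var_pos) != variant$ref_allele) {
    stop("context base at the variant position (",
         substr(context, var_pos, var_pos), ") does not match ref allele (",
         variant$ref_allele, ")")
  }
  alt_context <- context
  substr(alt_context, var_pos, var_pos) <- variant$alt_allele
  win_offsets <- seq(max(1L, var_pos - L + 1L), min(var_pos, n - L + 1L))
  ref <- pwm_best_logodds(pwm, context, background, offsets = win_offsets)
  alt <- pwm_best_logodds(pwm, alt_context, background, offsets = win_offsets)
  delta <- alt$score - ref$score
  tibble(pwm_id = pwm$tf_name, tf_name = pwm$tf_name,
         ref_score = ref$score, alt_score = alt$score, delta = delta,
         altered = abs(delta) >= threshold)
}

#' Read a TF alias table
#'
#' Two-column TSV (`alias`, `canonical`) mapping database-specific motif
#' names onto canonical TF symbols (e.g. HNF3beta is a synonym of FOXA2).
#' Matching is case-insensitive.
#'
#' @param path TSV path; defaults to the small alias table shipped with
#'   the package.
#' @return Named character vector: `names()` are upper-cased aliases,
#'   values are canonical symbols.
#' @export
read_alias_map <- function(path = system.file("extdata", "tf_aliases.tsv",
                                              package = "proxyreg")) {
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  setNames(toupper(tab$canonical), toupper(tab$alias))
}

canonical_tf <- function(name, alias_map = NULL) {
  up <- toupper(trimws(name))
  if (is.null(alias_map) || length(alias_map) == 0) return(up)
  mapped <- alias_map[up]
  ifelse(is.na(mapped), up, toupper(unname(mapped)))
}

#' Is a motif's TF the same factor as one of the bound TFs?
#'
#' Decides "matched TF motif" / "matched DNase footprint": true iff the
#' motif's TF, after alias canonicalization, equals (case-insensitively)
#' the canonical name of any ChIP-seq-bound TF at the site.
#'
#' @param motif_tf Motif TF name.
#' @param bound_tfs Character vector of bound TF names (may be empty).
#' @param alias_map Alias map from [read_alias_map()], or NULL for exact
#'   case-insensitive matching only.
#' @return Logical scalar.
#' @examples
#' is_matched("HNF3beta", c("FOXA2", "EP300"),
#'            alias_map = c(HNF3BETA = "FOXA2"))
#' @export
is_matched <- function(motif_tf, bound_tfs, alias_map = NULL) {
  if (length(bound_tfs) == 0) return(FALSE)
  canonical_tf(motif_tf, alias_map) %in% canonical_tf(bound_tfs, alias_map)
}
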