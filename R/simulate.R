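#' Configuration for the block-LD haplotype panel simulator
#'
#' The simulator uses a founder-block model: each block carries a small
#' set of founder haplotypes with given frequencies, each simulated
#' haplotype picks one founder per block independently, so LD is perfect
#' (r^2 = 1) between block variants that segregate the founders and
#' vanishes between blocks (up to sampling noise ~ 1/n).
#'
#' @param n_haplotypes Number of haplotypes to draw (>= 2).
#' @param blocks List of block descriptions; each block is a list with
#'   `n_variants` and either `founders` (matrix of 0/1, founders x
#'   variants) plus `freqs`, or `n_founders` and `freqs` for random
#'   founders. Founder frequencies must sum to 1.
#' @param chrom Chromosome label for the simulated variants.
#' @param start_pos 1-based position of the first variant.
#' @param spacing_bp Distance between consecutive variants.
#' @param seed Integer seed; the same config and seed always reproduce
#'   the same panel.
#' @return List of class `panel_config`.
#' @export
panel_config <- function(n_haplotypes, blocks, chrom = "chr1",
                         start_pos = 1000000L, spacing_bp = 1000L,
                         seed = 1L) {
  stopifnot(n_haplotypes >= 2, length(blocks) >= 1)
  for (b in blocks) {
    stopifnot(!is.null(b$n_variants), b$n_variants >= 1)
    if (!is.null(b$freqs)) {
      stopifnot(abs(sum(b$freqs) - 1) < 1e-9)
    }
  }
  structure(list(n_haplotypes = as.integer(n_haplotypes), blocks = blocks,
                 chrom = chrom, start_pos = as.integer(start_pos),
                 spacing_bp = as.integer(spacing_bp),
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' @param config A [panel_config()].
#' @param population_label,panel_label Labels stored on the panel.
#' @return A [haplotype_panel()]; variants are named `simrs<k>`. Blocks
#'   whose founders do not segregate a variant leave it monomorphic,
#'   flagged in the panel's `monomorphic` field.
#' @export
simulate_panel <- function(config, population_label = "CEU",
                           panel_label = "simulated") {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_haplotypes
  cols <- list()
  for (b in config$blocks) {
    founders <- b$founders
    if (is.null(founders)) {
      nf <- if (!is.null(b$n_founders)) b$n_founders
            else if (!is.null(b$freqs)) length(b$freqs) else 2L
      founders <- matrix(rbinom(nf * b$n_variants, 1, 0.5),
                         nrow = nf, ncol = b$n_variants)
      # guarantee the first two founders differ at every site so that
      # two-founder blocks are polymorphic by construction
      if (nf >= 2) founders[2, ] <- 1L - founders[1, ]
    }
    freqs <- if (!is.null(b$freqs)) b$freqs
             else rep(1 / nrow(founders), nrow(founders))
    pick <- sample.int(nrow(founders), n, replace = TRUE, prob = freqs)
    cols[[length(cols) + 1L]] <- founders[pick, , drop = FALSE]
  }
  alleles <- do.call(cbind, cols)
  m <- ncol(alleles)
  variants <- tibble(
    rsid = paste0("simrs", seq_len(m)), chrom = config$chrom,
    pos = config$start_pos + (seq_len(m) - 1L) * config$spacing_bp,
    ref_allele = "A", alt_allele = "G", locus_label = NA_character_,
    region_class = "unknown"
  )
  haplotype_panel(alleles, variants, population_label, panel_label)
}

#' Construct a two-variant panel with a target r-squared
#'
#' Deterministic expected-count construction: with positive D, the AB
#' haplotype frequency is p_AB = p_a p_b + sqrt(r2 p_a(1-p_a) p_b(1-p_b));
#' haplotype counts are the expected counts rounded to integers, so the
#' recomputed r^2 matches the target to within the rounding error
#' (within 0.01 for n >= 2000).
#'
#' @param target_r2 Desired squared correlation in \[0, 1\].
#' @param p_a,p_b Alternate-allele frequencies at the two sites.
#' @param n_haplotypes Number of haplotypes.
#' @return A two-variant [haplotype_panel()].
#' @export
construct_pair_with_r2 <- function(target_r2, p_a = 0.5, p_b = 0.5,
                                   n_haplotypes = 2000L) {
  stopifnot(target_r2 >= 0, target_r2 <= 1,
            p_a > 0, p_a < 1, p_b > 0, p_b < 1, n_haplotypes >= 4)
  d <- sqrt(target_r2 * p_a * (1 - p_a) * p_b * (1 - p_b))
  d_max <- min(p_a * (1 - p_b), (1 - p_a) * p_b)
  if (d > d_max + 1e-12) {
    stop("target r2 = ", target_r2, " infeasible at p_a = ", p_a,
         ", p_b = ", p_b, "; maximum achievable r2 is ",
         signif((d_max^2) / (p_a * (1 - p_a) * p_b * (1 - p_b)), 4))
  }
  p_ab <- p_a * p_b + d
  n <- as.integer(n_haplotypes)
  n_ab <- round(n * p_ab)
  n_a <- round(n * p_a)
  n_b <- round(n * p_b)
  n_a0 <- n_a - n_ab   # haplotype (1, 0)
  n_0b <- n_b - n_ab   # haplotype (0, 1)
  n_00 <- n - n_ab - n_a0 - n_0b
  if (min(n_ab, n_a0, n_0b, n_00) < 0) {
    stop("expected counts round to a negative cell; increase n_haplotypes")
  }
  alleles <- rbind(
    matrix(rep(c(1L, 1L), n_ab), ncol = 2, byrow = TRUE),
    matrix(rep(c(1L, 0L), n_a0), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), n_0b), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 0L), n_00), ncol = 2, byrow = TRUE)
  )
  variants <- tibble(
    rsid = c("pairA", "pairB"), chrom = "chr1",
    pos = c(1000000L, 1001000L), ref_allele = "A", alt_allele = "G",
    locus_label = NA_character_, region_class = "unknown"
  )
  haplotype_panel(alleles, variants, panel_label = "constructed")
}

#' Plant evidence tracks realizing a target category
#'
#' Builds the minimal set of annotation tracks and eQTL rows such that
#' [collect_evidence()] + [derive_flags()] + [classify()] on the variant
#' returns exactly `target`. Matched-motif/footprint categories use a TF
#' name equal to the planted peak's TF; unmatched ones use disjoint
#' names. For "ND" no tracks are planted.
#'
#' @param variant One-row variant tibble.
#' @param target A label from `category_levels()`.
#' @param tf Bound TF name used for the planted peak.
#' @return List with `tracks` (interval tibble across kinds, scoring
#'   source) and `eqtls` (eQTL tibble, possibly empty).
#' @export
plant_evidence <- function(variant, target, tf = "TFX") {
  target <- match.arg(target, category_levels())
  p <- variant$pos
  iv <- function(kind, name = NA_character_, pwm_id = NA_character_,
                 strand = NA_character_) {
    tibble(chrom = variant$chrom, start = p - 50L, end = p + 50L,
           name = name, cell_type = "SimCell", pwm_id = pwm_id,
           strand = strand, kind = kind, source = "scoring")
  }
  other <- paste0(tf, "_OTHER")
  need <- switch(target,
    "1a" = list(eqtl = TRUE, tf = TRUE, motif = tf, fp = tf, peak = TRUE),
    "1b" = list(eqtl = TRUE, tf = TRUE, motif = other,
                fp = paste0(other, "2"), peak = TRUE),
    "1c" = list(eqtl = TRUE, tf = TRUE, motif = tf, fp = NULL, peak = TRUE),
    "1d" = list(eqtl = TRUE, tf = TRUE, motif = other, fp = NULL,
                peak = TRUE),
    "1e" = list(eqtl = TRUE, tf = TRUE, motif = tf, fp = NULL, peak = FALSE),
    "1f" = list(eqtl = TRUE, tf = FALSE, motif = NULL, fp = NULL,
                peak = TRUE),
    "2a" = list(eqtl = FALSE, tf = TRUE, motif = tf, fp = tf, peak = TRUE),
    "2b" = list(eqtl = FALSE, tf = TRUE, motif = other,
                fp = paste0(other, "2"), peak = TRUE),
    "2c" = list(eqtl = FALSE, tf = TRUE, motif = tf, fp = NULL, peak = TRUE),
    "3a" = list(eqtl = FALSE, tf = TRUE, motif = other, fp = NULL,
                peak = TRUE),
    "3b" = list(eqtl = FALSE, tf = TRUE, motif = tf, fp = NULL,
                peak = FALSE),
    "4" = list(eqtl = FALSE, tf = TRUE, motif = NULL, fp = NULL,
               peak = TRUE),
    "5" = list(eqtl = FALSE, tf = TRUE, motif = NULL, fp = NULL,
               peak = FALSE),
    "6" = list(eqtl = FALSE, tf = FALSE, motif = other, fp = NULL,
               peak = FALSE),
    "ND" = list(eqtl = FALSE, tf = FALSE, motif = NULL, fp = NULL,
                peak = FALSE)
  )
  tracks <- list()
  if (need$tf) tracks <- c(tracks, list(iv("tf_peak", name = tf)))
  if (need$peak) tracks <- c(tracks, list(iv("dnase_peak")))
  if (!is.null(need$motif)) {
    tracks <- c(tracks, list(iv("motif_instance", name = need$motif,
                                pwm_id = paste0(need$motif, "_pwm"),
                                strand = "+")))
  }
  if (!is.null(need$fp)) {
    tracks <- c(tracks, list(iv("dnase_footprint", name = need$fp)))
  }
  tracks <- if (length(tracks) > 0) bind_rows(tracks) else
    tibble(chrom = character(), start = integer(), end = integer(),
           name = character(), cell_type = character(),
           pwm_id = character(), strand = character(), kind = character(),
           source = character())
  eqtls <- if (need$eqtl) {
    tibble(rsid = variant$rsid, chrom = variant$chrom, pos = variant$pos,
           target_gene = ifelse(is.na(variant$locus_label), "GENE1",
                                variant$locus_label),
           tissue = "SimTissue", statistic = 1e-6, source = "scoring")
  } else {
    tibble(rsid = character(), chrom = character(), pos = integer(),
           target_gene = character(), tissue = character(),
           statistic = double(), source = character())
  }
  list(tracks = tracks, eqtls = eqtls)
}
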