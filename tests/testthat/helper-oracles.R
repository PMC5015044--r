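# Independent oracles used across the suite. Each takes a deliberately
# different route from the implementation it checks.

# LD via the sample correlation of allele indicators (cor()^2), not via
# haplotype-frequency algebra.
ld_oracle_r2 <- function(x, y) {
  unname(stats::cor(x, y)^2)
}

# random polymorphic panel; every column carries both alleles
random_panel <- function(n_hap, n_var, chrom = "chrO") {
  m <- matrix(rbinom(n_hap * n_var, 1, runif(1, 0.2, 0.8)),
              nrow = n_hap, ncol = n_var)
  for (j in seq_len(n_var)) {
    if (length(unique(m[, j])) == 1L) {
      m[1, j] <- 1L - m[1, j]
    }
  }
  haplotype_panel(
    m,
    tibble::tibble(rsid = paste0("orc", seq_len(n_var)), chrom = chrom,
                   pos = 1000L * seq_len(n_var), ref_allele = "A",
                   alt_allele = "G", locus_label = NA_character_,
                   region_class = "unknown"),
    panel_label = "oracle"
  )
}

# Declarative re-statement of the decision table: each category lists the
# flags it requires plus an optional any-of group. The oracle collects
# every satisfied category and returns the best (minimum ordinal) one,
# instead of first-match short-circuiting.
classifier_rule_table <- list(
  list(label = "1a", all = c("has_eqtl", "has_tf_binding",
                             "has_motif_matched", "has_footprint_matched",
                             "has_dnase_peak")),
  list(label = "1b", all = c("has_eqtl", "has_tf_binding", "has_motif_any",
                             "has_footprint", "has_dnase_peak")),
  list(label = "1c", all = c("has_eqtl", "has_tf_binding",
                             "has_motif_matched", "has_dnase_peak")),
  list(label = "1d", all = c("has_eqtl", "has_tf_binding", "has_motif_any",
                             "has_dnase_peak")),
  list(label = "1e", all = c("has_eqtl", "has_tf_binding",
                             "has_motif_matched")),
  list(label = "1f", all = "has_eqtl",
       any = c("has_tf_binding", "has_dnase_peak")),
  list(label = "2a", all = c("has_tf_binding", "has_motif_matched",
                             "has_footprint_matched", "has_dnase_peak")),
  list(label = "2b", all = c("has_tf_binding", "has_motif_any",
                             "has_footprint", "has_dnase_peak")),
  list(label = "2c", all = c("has_tf_binding", "has_motif_matched",
                             "has_dnase_peak")),
  list(label = "3a", all = c("has_tf_binding", "has_motif_any",
                             "has_dnase_peak")),
  list(label = "3b", all = c("has_tf_binding", "has_motif_matched")),
  list(label = "4", all = c("has_tf_binding", "has_dnase_peak")),
  list(label = "5", all = character(), any = c("has_tf_binding",
                                               "has_dnase_peak")),
  list(label = "6", all = "has_motif_hit")
)

classify_oracle <- function(flags) {
  f <- as.list(flags)
  satisfied <- vapply(classifier_rule_table, function(rule) {
    all(unlist(f[rule$all])) &&
      (is.null(rule$any) || any(unlist(f[rule$any])))
  }, logical(1))
  if (!any(satisfied)) return("ND")
  labels <- vapply(classifier_rule_table, `[[`, character(1), "label")
  labels[satisfied][which.min(category_ordinal(labels[satisfied]))]
}

# all flag combinations satisfying the implication invariants
valid_flag_grid <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  names(g) <- c("has_eqtl", "has_tf_binding", "has_motif_any",
                "has_motif_matched", "has_footprint",
                "has_footprint_matched", "has_dnase_peak", "has_motif_hit")
  ok <- (!g$has_motif_matched | g$has_motif_any) &
    (!g$has_motif_any | g$has_motif_hit) &
    (!g$has_footprint_matched | g$has_footprint)
  g[ok, , drop = FALSE]
}

# exhaustive per-offset PWM scan, scoring with prod()/log2 and an
# explicit string reverse complement
revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

pwm_scan_oracle <- function(pwm_obj, sequence, background = rep(0.25, 4)) {
  L <- nrow(pwm_obj$probs)
  bases <- c("A", "C", "G", "T")
  best <- -Inf
  for (o in seq_len(nchar(sequence) - L + 1)) {
    win <- substr(sequence, o, o + L - 1)
    for (s in list(win, revcomp_chr(win))) {
      chars <- strsplit(s, "")[[1]]
      p <- prod(vapply(seq_len(L), function(i) {
        pwm_obj$probs[i, chars[i]] / background[match(chars[i], bases)]
      }, numeric(1)))
      best <- max(best, log2(p))
    }
  }
  best
}

# linear-scan overlap oracle over a raw track tibble
scan_overlaps_oracle <- function(tracks, chrom, pos) {
  hit <- tracks$chrom == chrom & pos_in_interval(pos, tracks$start,
                                                 tracks$end)
  tracks[hit, , drop = FALSE]
}

mk_track <- function(kind, chrom, start, end, name = NA_character_,
                     source = "scoring", pwm_id = NA_character_,
                     strand = NA_character_) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), name = name, cell_type = "Cell",
                 pwm_id = pwm_id, strand = strand, kind = kind,
                 source = source)
}

sim_variant <- function(rsid = "rsV", chrom = "chr1", pos = 5000L,
                        ref = "C", alt = "T", locus = NA_character_) {
  variant_table(rsid, chrom, pos, ref, alt, locus_label = locus)
}
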