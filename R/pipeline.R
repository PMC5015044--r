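#' Pipeline run configuration
#'
#' Collects thresholds and input/output paths for [run_pipeline()].
#' Defaults mirror the standard post-GWAS settings: genome-wide
#' significance p < 5e-8, proxy expansion at r^2 >= 0.8 (with 0.9 and 1.0
#' reported as bins), a 500 kb proxy search window, and a 1-bit
#' allele-differential log-odds change to call a motif altered.
#'
#' @param studies Named list: study label -> index-SNP TSV path.
#' @param panels List of panels, each `list(path =, panel_label =,
#'   population_label =)` pointing at a phased VCF.
#' @param tracks_scoring,tracks_secondary Named lists: track kind (see
#'   `track_kinds()`) -> TSV path, for the scoring and the secondary
#'   annotation source.
#' @param eqtl_scoring,eqtl_secondary Optional eQTL TSV paths.
#' @param alias_path TF alias TSV; defaults to the bundled table.
#' @param out_dir Directory for report files (created if needed).
#' @param p_threshold GWAS significance threshold (strict <).
#' @param r2_threshold Proxy inclusion threshold (r^2 >=).
#' @param window_bp Proxy search window around each index SNP.
#' @param motif_delta_threshold_bits Bits of log-odds change calling a
#'   motif altered.
#' @param seed Integer seed recorded with the run.
#' @return List of class `run_config`.
#' @export
run_config <- function(studies, panels, tracks_scoring = list(),
                       tracks_secondary = list(), eqtl_scoring = NULL,
                       eqtl_secondary = NULL, alias_path = NULL,
                       out_dir = tempfile("proxyreg_run_"),
                       p_threshold = 5e-8, r2_threshold = 0.8,
                       window_bp = 500000L,
                       motif_delta_threshold_bits = 1.0, seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold > 0, r2_threshold <= 1)
  structure(list(
    studies = studies, panels = panels, tracks_scoring = tracks_scoring,
    tracks_secondary = tracks_secondary, eqtl_scoring = eqtl_scoring,
    eqtl_secondary = eqtl_secondary, alias_path = alias_path,
    out_dir = out_dir, p_threshold = p_threshold,
    r2_threshold = r2_threshold, window_bp = as.integer(window_bp),
    motif_delta_threshold_bits = motif_delta_threshold_bits,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Select genome-wide significant index SNPs across studies
#'
#' Applies the strict significance filter (p < threshold), drops
#' deficient entries (those without a proper rsid) with a logged count,
#' and deduplicates SNPs reported by several studies on rsid — the first
#' study's record survives with `study_label` set to "both".
#'
#' @param studies List of index-SNP tibbles from [read_index_snps()].
#' @param p_threshold Significance threshold, strict inequality.
#' @return Deduplicated index-SNP tibble.
#' @export
select_index_snps <- function(studies, p_threshold = 5e-8) {
  all <- bind_rows(studies)
  if (nrow(all) == 0) return(all)
  n_def <- sum(all$deficient)
  if (n_def > 0) {
    message("select_index_snps: dropping ", n_def, " deficient entr",
            if (n_def == 1) "y" else "ies", " without an rsid")
  }
  kept <- filter(all, !deficient, gwas_pvalue < p_threshold)
  dup <- duplicated(kept$rsid)
  shared <- unique(kept$rsid[dup])
  out <- kept[!dup, , drop = FALSE]
  out$study_label[out$rsid %in% shared] <- "both"
  message("select_index_snps: ", nrow(out), " index SNPs selected (",
          length(shared), " shared across studies)")
  out
}

#' Run the prioritization pipeline end to end
#'
#' Stages: study selection, LD proxy expansion per panel, panel merge,
#' evidence collection against the scoring source, secondary-source
#' annotation merge, flag derivation, category classification, and the
#' three report tables. Per-stage row counts are logged with
#' `message()`; given the same configuration and inputs the outputs are
#' byte-identical across reruns.
#'
#' @param config A [run_config()].
#' @return (Invisibly) list with `index_snps`, `proxies`, `scored`,
#'   `annotation`, `ld_report`, `distribution`, `locus_summary`, and
#'   `summary` (the counts also written as YAML). Report TSVs and
#'   `summary.yaml` are written to `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  studies <- lapply(names(config$studies), function(lbl) {
    read_index_snps(config$studies[[lbl]], study_label = lbl)
  })
  message("stage select: ", sum(vapply(studies, nrow, 1L)),
          " study entries read")
  index_snps <- select_index_snps(studies, config$p_threshold)

  panels <- lapply(config$panels, function(p) {
    read_vcf_panel(p$path,
                   population_label = p$population_label %||% "CEU",
                   panel_label = p$panel_label %||% basename(p$path))
  })
  proxy_sets <- list()
  for (panel in panels) {
    present <- intersect(index_snps$rsid, panel$variants$rsid)
    sets <- lapply(present, function(rs) {
      expand_proxies(panel, rs, r2_threshold = config$r2_threshold,
                     window_bp = config$window_bp)
    })
    n_found <- sum(vapply(sets, nrow, 1L))
    message("stage expand: panel ", panel$panel_label, ": ",
            length(present), "/", nrow(index_snps), " index SNPs, ",
            n_found, " proxy records")
    proxy_sets <- c(proxy_sets, sets)
  }
  missing_idx <- setdiff(index_snps$rsid,
                         unlist(lapply(panels,
                                       function(p) p$variants$rsid)))
  if (length(missing_idx) > 0) {
    warning("index SNP(s) absent from every panel: ",
            paste(missing_idx, collapse = ", "))
  }
  proxies <- merge_proxy_sets(proxy_sets)
  # attach the index SNP's locus label to each proxy
  proxies <- left_join(proxies,
                       tibble(index_rsid = index_snps$rsid,
                              locus = index_snps$locus_label),
                       by = "index_rsid")
  message("stage merge: ", nrow(proxies), " unique proxy records")

  read_kind_tracks <- function(paths, source) {
    bind_rows(lapply(names(paths), function(k) {
      read_track(paths[[k]], k, source = source)
    }))
  }
  scoring_tracks <- read_kind_tracks(config$tracks_scoring, "scoring")
  secondary_tracks <- read_kind_tracks(config$tracks_secondary, "secondary")
  idx_scoring <- build_interval_index(scoring_tracks)
  idx_secondary <- build_interval_index(secondary_tracks)
  eqtl_s <- if (!is.null(config$eqtl_scoring))
    read_eqtl(config$eqtl_scoring, "scoring") else NULL
  eqtl_2 <- if (!is.null(config$eqtl_secondary))
    read_eqtl(config$eqtl_secondary, "secondary") else NULL
  alias_map <- if (!is.null(config$alias_path))
    read_alias_map(config$alias_path) else read_alias_map()

  # unique variants to annotate (proxies keyed by proxy rsid)
  variant_rows <- proxies %>%
    distinct(proxy_rsid, chrom, pos) %>%
    rename(rsid = "proxy_rsid")
  variant_rows$ref_allele <- "N"; variant_rows$alt_allele <- "."
  variant_rows$locus_label <- proxies$locus[
    match(variant_rows$rsid, proxies$proxy_rsid)]
  variant_rows$region_class <- "unknown"

  profiles <- lapply(seq_len(nrow(variant_rows)), function(i) {
    v <- variant_rows[i, , drop = FALSE]
    prim <- collect_evidence(v, idx_scoring, eqtl_s)
    sec <- collect_evidence(v, idx_secondary, eqtl_2)
    merge_annotation_sources(prim, sec)
  })
  message("stage annotate: ", length(profiles), " variants annotated")

  scored <- bind_rows(lapply(profiles, function(pr) {
    fl <- derive_flags(pr, alias_map = alias_map)
    cbind(pr$variant[, c("rsid", "chrom", "pos")],
          tibble(label = classify(fl)),
          as_tibble(as.list(setNames(as.integer(fl), names(fl)))))
  }))
  scored$major <- category_major(scored$label)
  n_nd <- sum(scored$label == "ND")
  message("stage classify: ", nrow(scored), " queried = ",
          nrow(scored) - n_nd, " scored + ", n_nd, " ND")
  stopifnot(nrow(scored) == (nrow(scored) - n_nd) + n_nd)

  annotation <- annotation_table(profiles)
  with_label <- scored[scored$label != "ND", c("rsid", "label")]
  ld_report <- ld_score_table(proxies, with_label)
  distribution <- category_distribution(scored[scored$label != "ND", ,
                                               drop = FALSE],
                                        total_queried = nrow(scored))
  loci <- if (nrow(ld_report) > 0) locus_summary(ld_report) else NULL

  write_report(annotation, file.path(config$out_dir, "annotation.tsv"))
  write_report(ld_report, file.path(config$out_dir, "ld_categories.tsv"))
  write_report(scored, file.path(config$out_dir, "scored_variants.tsv"))
  write_report(tibble(label = names(distribution$counts),
                      count = unname(distribution$counts)),
               file.path(config$out_dir, "category_distribution.tsv"))
  if (!is.null(loci)) {
    write_report(loci, file.path(config$out_dir, "locus_summary.tsv"))
  }
  summary <- list(
    n_index_snps = nrow(index_snps),
    n_proxies = nrow(proxies),
    n_queried = nrow(scored),
    n_scored = nrow(scored) - n_nd,
    n_nd = n_nd,
    n_category1 = sum(scored$major == 1, na.rm = TRUE),
    n_score_le2 = sum(scored$major <= 2, na.rm = TRUE)
  )
  yaml::write_yaml(summary, file.path(config$out_dir, "summary.yaml"))
  invisible(list(index_snps = index_snps, proxies = proxies,
                 scored = as_tibble(scored), annotation = annotation,
                 ld_report = ld_report, distribution = distribution,
                 locus_summary = loci, summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
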