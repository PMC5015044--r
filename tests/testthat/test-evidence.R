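test_that("point queries honor the half-open boundary rule", {
  idx <- build_interval_index(mk_track("tf_peak", "chr1", 99, 150, "TFX"))
  expect_equal(nrow(query_evidence_index(idx, "chr1", 100)), 1L)  # 99 <= 99 < 150
  idx2 <- build_interval_index(mk_track("tf_peak", "chr1", 100, 150, "TFX"))
  expect_equal(nrow(query_evidence_index(idx2, "chr1", 100)), 0L) # 99 < 100
  expect_equal(nrow(query_evidence_index(idx2, "chr1", 101)), 1L)
  expect_equal(nrow(query_evidence_index(idx2, "chr1", 150)), 1L) # 149 < 150
  expect_equal(nrow(query_evidence_index(idx2, "chr1", 151)), 0L)
})

test_that("index queries equal a linear scan over random interval fixtures", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 40
    starts <- sample(0:500, n, replace = TRUE)
    tracks <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      mk_track(sample(c("tf_peak", "dnase_peak", "histone_mark"), 1),
               sample(c("chr1", "chr2"), 1), starts[i],
               starts[i] + sample(1:80, 1), paste0("N", i))
    }))
    idx <- build_interval_index(tracks)
    for (q in 1:12) {
      chrom <- sample(c("chr1", "chr2"), 1)
      pos <- sample(1:600, 1)
      got <- query_evidence_index(idx, chrom, pos)
      want <- scan_overlaps_oracle(tracks, chrom, pos)
      expect_setequal(got$name, want$name)
    }
  }
})

test_that("collect_evidence gathers overlapping records and eQTL rows", {
  v <- sim_variant("rs3138142x", "chr12", 56115584L)
  tracks <- dplyr::bind_rows(
    mk_track("tf_peak", "chr12", 56115500, 56115700, "POLR2A"),
    mk_track("dnase_peak", "chr12", 56115000, 56116000),
    mk_track("tf_peak", "chr12", 56200000, 56200100, "CTCF")  # elsewhere
  )
  eqtls <- tibble::tibble(rsid = "rs3138142x", chrom = "chr12",
                          pos = 56115584L, target_gene = "RDH5",
                          tissue = "retina", statistic = 1e-9,
                          source = "scoring")
  pr <- collect_evidence(v, build_interval_index(tracks), eqtls)
  expect_setequal(pr$records$kind, c("tf_peak", "dnase_peak", "eqtl"))
  expect_equal(pr$records$name[pr$records$kind == "tf_peak"], "POLR2A")
  expect_equal(pr$eqtl_targets, "RDH5")
})

test_that("eQTL matching falls back to position when the rsid is absent", {
  v <- sim_variant("rs_unseen", "chr2", 500L)
  eqtls <- tibble::tibble(rsid = "rs_other", chrom = "chr2", pos = 500L,
                          target_gene = "GENE2", tissue = NA_character_,
                          statistic = NA_real_, source = "scoring")
  pr <- collect_evidence(v, build_interval_index(list()), eqtls)
  expect_equal(pr$eqtl_targets, "GENE2")
})

test_that("a variant overlapping nothing yields an empty profile", {
  v <- sim_variant(pos = 99999L)
  pr <- collect_evidence(v, build_interval_index(list()), NULL)
  expect_equal(nrow(pr$records), 0L)
  expect_length(pr$eqtl_targets, 0L)
})

test_that("a motif-only overlap yields a single motif record", {
  v <- sim_variant(pos = 120L)
  idx <- build_interval_index(mk_track("motif_instance", "chr1", 100, 140,
                                       "SOX2", pwm_id = "sox2_pwm",
                                       strand = "-"))
  pr <- collect_evidence(v, idx, NULL)
  expect_equal(pr$records$kind, "motif_instance")
  expect_equal(pr$records$strand, "-")
})

test_that("source merge tags shared records 'both' and keeps secondary out of scoring", {
  v <- sim_variant(pos = 120L)
  prim <- collect_evidence(v, build_interval_index(
    mk_track("tf_peak", "chr1", 100, 140, "POLR2A")), NULL)
  sec <- collect_evidence(v, build_interval_index(dplyr::bind_rows(
    mk_track("tf_peak", "chr1", 110, 130, "POLR2A", source = "secondary"),
    mk_track("tf_peak", "chr1", 110, 130, "CTCF", source = "secondary"))),
    NULL)
  merged <- merge_annotation_sources(prim, sec)
  r <- merged$records
  expect_equal(r$source[r$name == "POLR2A"], "both")
  expect_equal(r$source[r$name == "CTCF"], "secondary")
  # scoring flags see POLR2A but not CTCF
  fl <- derive_flags(merged)
  expect_true(fl[["has_tf_binding"]])
  expect_false(is_matched("CTCF",
                          r$name[r$kind == "tf_peak" &
                                   r$source %in% c("scoring", "both")]))
})

test_that("merging an empty secondary profile leaves the primary unchanged", {
  v <- sim_variant(pos = 120L)
  prim <- collect_evidence(v, build_interval_index(
    mk_track("tf_peak", "chr1", 100, 140, "POLR2A")), NULL)
  empty <- collect_evidence(v, build_interval_index(list()), NULL)
  merged <- merge_annotation_sources(prim, empty)
  expect_equal(nrow(merged$records), 1L)
  expect_equal(merged$records$source, "scoring")
})

test_that("secondary-only motifs never change the assigned category", {
  # eQTL + TF peak + DNase peak from the scoring source; motifs only from
  # the secondary source: category must stay 1f, not become 1d
  v <- sim_variant("rs_sec", "chr12", 56114768L)
  planted <- plant_evidence(v, "1f")
  tf <- mk_track("tf_peak", "chr12", 56114700, 56114800, "POLR2A")
  prim <- collect_evidence(v, build_interval_index(
    dplyr::bind_rows(planted$tracks, tf)), planted$eqtls)
  sec <- collect_evidence(v, build_interval_index(dplyr::bind_rows(
    mk_track("motif_instance", "chr12", 56114700, 56114800, "BCL",
             source = "secondary"),
    mk_track("motif_instance", "chr12", 56114700, 56114800, "NRSF",
             source = "secondary"))), NULL)
  merged <- merge_annotation_sources(prim, sec)
  fl <- derive_flags(merged)
  expect_false(fl[["has_motif_any"]])
  expect_equal(classify(fl), "1f")
})

test_that("profiles for different variants refuse to merge", {
  a <- collect_evidence(sim_variant("rsA", pos = 10L),
                        build_interval_index(list()), NULL)
  b <- collect_evidence(sim_variant("rsB", pos = 20L),
                        build_interval_index(list()), NULL)
  expect_error(merge_annotation_sources(a, b), "different variants")
})
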