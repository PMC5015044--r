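case_ld <- function() load_case_study()$ld_categories

test_that("category distribution reproduces the case-study counts and conserves totals", {
  fx <- load_case_study()
  scored <- expand_distribution(fx$distribution)
  expect_equal(nrow(scored), 662L)
  dist <- category_distribution(scored, total_queried = 868L)
  expect_equal(unname(dist$counts[c("1a", "1b", "1d", "1f")]),
               c(1L, 5L, 5L, 25L))
  expect_equal(unname(dist$counts[["ND"]]), 206L)
  expect_equal(sum(dist$counts), dist$total_queried)
})

test_that("category distribution conserves totals on random inputs and handles empties", {
  set.seed(71)
  for (rep in 1:10) {
    n <- sample(0:40, 1)
    scored <- tibble::tibble(
      rsid = paste0("v", seq_len(n)),
      label = sample(category_levels(), n, replace = TRUE))
    extra <- sample(0:10, 1)
    dist <- category_distribution(scored, total_queried = n + extra)
    expect_equal(sum(dist$counts), n + extra)
  }
  empty <- category_distribution(tibble::tibble(label = character()), 0)
  expect_true(all(empty$counts == 0L))
  expect_error(category_distribution(tibble::tibble(label = "1a"), 0),
               "smaller")
})

test_that("the LD/category report puts self-rows first and floors r2 into bins", {
  proxies <- tibble::tibble(
    index_rsid = "rsIDX",
    proxy_rsid = c("rsIDX", "rsP1", "rsP2"),
    chrom = "chr1", pos = c(100L, 200L, 300L),
    r2 = c(1.0, 0.93, 0.81), d_prime = 1,
    distance_bp = c(0L, 100L, 200L), panel = "1000G",
    locus = "GENE")
  scored <- tibble::tibble(rsid = c("rsP2", "rsIDX", "rsP1"),
                           label = c("4", "1d", "2b"))
  rep_tab <- ld_score_table(proxies, scored)
  expect_equal(rep_tab$proxy_rsid[1], "rsIDX")   # self-row first
  expect_true(rep_tab$is_index[1])
  expect_equal(rep_tab$r2_bin, c(1.0, 0.9, 0.8)) # 0.93 floors to 0.9
  expect_equal(rep_tab$label[rep_tab$proxy_rsid == "rsP1"], "2b")
})

test_that("a scored variant without a proxy record is an error naming it", {
  proxies <- tibble::tibble(index_rsid = "rsIDX", proxy_rsid = "rsIDX",
                            chrom = "chr1", pos = 100L, r2 = 1,
                            d_prime = 1, distance_bp = 0L, panel = "p")
  scored <- tibble::tibble(rsid = c("rsIDX", "rs_orphan"), label = "5")
  expect_error(ld_score_table(proxies, scored), "rs_orphan")
})

test_that("locus summary reproduces the case-study per-locus counts", {
  fx <- load_case_study()
  ls <- locus_summary(fx$ld_categories,
                      proxy_counts = fx$locus_proxy_counts)
  expect_equal(nrow(ls), 5L)
  expect_equal(ls$n_category1[ls$locus == "CD55"], 13L)
  expect_equal(ls$n_category1[ls$locus == "CNDP2"], 15L)
  expect_equal(ls$n_category1[ls$locus == "MYO1D"], 3L)
  expect_equal(ls$n_proxies_investigated[ls$locus == "MYO1D"], 34L)
  # the RDH5 locus carries two index SNPs but is counted once
  expect_equal(sum(ls$locus == "RDH5"), 1L)
  expect_equal(ls$index_rsids[ls$locus == "RDH5"], "rs3138142,rs3138144")
  expect_equal(sum(ls$n_index_in_category1), 4L)
})

test_that("locus summary is invariant under row permutation", {
  fx <- case_ld()
  set.seed(13)
  shuffled <- fx[sample(nrow(fx)), ]
  expect_equal(locus_summary(shuffled), locus_summary(fx))
})

test_that("annotation rows render the two-source convention", {
  v <- sim_variant("rs4844592x", "chr1", 207501210L, "T", "A",
                   locus = "CD55")
  prim <- collect_evidence(v, build_interval_index(dplyr::bind_rows(
    mk_track("tf_peak", "chr1", 207501100, 207501300, "POLR2A"),
    mk_track("dnase_peak", "chr1", 207501000, 207502000),
    mk_track("histone_mark", "chr1", 207500000, 207503000, "H3K27ac"))),
    tibble::tibble(rsid = "rs4844592x", chrom = "chr1", pos = 207501210L,
                   target_gene = "CD55", tissue = NA_character_,
                   statistic = NA_real_, source = "scoring"))
  sec <- collect_evidence(v, build_interval_index(dplyr::bind_rows(
    mk_track("tf_peak", "chr1", 207501100, 207501300, "POLR2A",
             source = "secondary"),
    mk_track("motif_instance", "chr1", 207501100, 207501300, "HDAC2",
             source = "secondary"))), NULL)
  merged <- merge_annotation_sources(prim, sec)
  tab <- annotation_table(list(merged))
  expect_equal(tab$protein_bound, "POLR2A*")
  expect_equal(tab$motifs_altered, "-; HDAC2")  # secondary-only motifs
  expect_equal(tab$histone_marked, "+")
  expect_equal(tab$dnase, "+")
  expect_equal(tab$eqtl, "+")
})

test_that("an empty profile renders the all-absent row with a blank protein cell", {
  v <- sim_variant("rs_empty", "chr9", 123L)
  pr <- collect_evidence(v, build_interval_index(list()), NULL)
  tab <- annotation_table(list(pr))
  expect_equal(tab$histone_marked, "-")
  expect_equal(tab$dnase, "-")
  expect_equal(tab$eqtl, "-")
  expect_equal(tab$motifs_altered, "-")
  expect_equal(tab$protein_bound, "")
})

test_that("the semicolon/asterisk cell convention round-trips through its parser", {
  render <- proxyreg:::render_source_cell
  parse <- proxyreg:::parse_source_cell
  set.seed(37)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    names <- paste0("TF", sample(100, n))
    sources <- sample(c("scoring", "both", "secondary"), n, replace = TRUE)
    # rendering groups scoring/both before secondary
    ord <- order(match(sources, c("scoring", "both", "secondary")) > 2)
    cell <- render(names[ord], sources[ord])
    back <- parse(cell)
    expect_setequal(paste(back$name, back$source),
                    paste(names, sources))
  }
  expect_equal(nrow(proxyreg:::parse_source_cell("-")), 0L)
})
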