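consensus_pwm <- function(consensus, p = 0.97, pseudocount = 0) {
  bases <- c("A", "C", "G", "T")
  probs <- t(vapply(strsplit(consensus, "")[[1]], function(b) {
    row <- rep((1 - p) / 3, 4)
    row[match(b, bases)] <- p
    row
  }, numeric(4)))
  pwm("TFX", probs, pseudocount = pseudocount)
}

test_that("a uniform PWM scores 0 at every offset against uniform background", {
  u <- pwm("UNIF", matrix(0.25, nrow = 5, ncol = 4), pseudocount = 0)
  hit <- pwm_best_logodds(u, "ACGTACGTACG")
  expect_equal(hit$score, 0)
  expect_equal(hit$offset, 1L)   # ties break to the smallest offset
  expect_equal(hit$strand, "+")  # then to the forward strand
})

test_that("a consensus match scores the closed-form log-odds sum", {
  pw <- consensus_pwm("ACGT")
  hit <- pwm_best_logodds(pw, "TTACGTTT")
  expect_equal(hit$score, 4 * log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(hit$offset, 3L)
  expect_equal(hit$strand, "+")
})

test_that("best log-odds agrees with the exhaustive per-offset oracle", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:15) {
    L <- sample(4:8, 1)
    probs <- matrix(stats::rexp(L * 4), ncol = 4)
    probs <- probs / rowSums(probs)
    pw <- pwm("RND", probs, pseudocount = 0.01)
    seqn <- paste(sample(bases, sample(L:50, 1), replace = TRUE),
                  collapse = "")
    expect_equal(pwm_best_logodds(pw, seqn)$score,
                 pwm_scan_oracle(pw, seqn), tolerance = 1e-9)
  }
})

test_that("a reverse-complemented sequence scores identically on the opposite strand", {
  pw <- consensus_pwm("ACGGT")
  fwd <- pwm_best_logodds(pw, "TTACGGTTT")
  rev <- pwm_best_logodds(pw, revcomp_chr("TTACGGTTT"))
  expect_equal(rev$score, fwd$score)
  expect_equal(rev$strand, "-")
})

test_that("non-ACGT sequence is rejected", {
  pw <- consensus_pwm("ACGT")
  expect_error(pwm_best_logodds(pw, "ACGNTACG"), "non-ACGT")
})

test_that("a consensus-destroying substitution yields the hand-computed delta", {
  pw <- consensus_pwm("ACGT")
  # context TTAC[G]TTTT: the consensus window AC*GT runs through the
  # variant; G -> C at the variant position destroys it, and the best
  # ref/alt windows share the offset, so the delta is exactly one
  # log-ratio
  v <- sim_variant(ref = "G", alt = "C", pos = 1000L)
  d <- motif_delta(pw, "TTACGTTTT", v, threshold = 1.0)
  expect_equal(d$delta, log2(0.01 / 0.97), tolerance = 1e-9)
  expect_true(d$altered)
  expect_lt(d$delta, 0)
})

test_that("delta is antisymmetric under swapping ref and alt alleles", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:10) {
    probs <- matrix(stats::rexp(20), ncol = 4)
    probs <- probs / rowSums(probs)
    pw <- pwm("RND", probs)
    ctx <- paste(sample(bases, 13, replace = TRUE), collapse = "")
    ref <- substr(ctx, 7, 7)
    alt <- sample(setdiff(bases, ref), 1)
    v_fwd <- sim_variant(ref = ref, alt = alt)
    ctx_alt <- ctx; substr(ctx_alt, 7, 7) <- alt
    v_rev <- sim_variant(ref = alt, alt = ref)
    d1 <- motif_delta(pw, ctx, v_fwd)$delta
    d2 <- motif_delta(pw, ctx_alt, v_rev)$delta
    expect_equal(d1, -d2, tolerance = 1e-9)
  }
})

test_that("a substitution the PWM cannot see leaves delta at 0", {
  u <- pwm("UNIF", matrix(0.25, nrow = 4, ncol = 4), pseudocount = 0)
  v <- sim_variant(ref = "A", alt = "T")
  d <- motif_delta(u, "CCCCACCCC", v, threshold = 1.0)
  expect_equal(d$delta, 0)
  expect_false(d$altered)
})

test_that("motif_delta validates the context against the variant", {
  pw <- consensus_pwm("ACGT")
  v <- sim_variant(ref = "G", alt = "C")
  expect_error(motif_delta(pw, "GGGACGTGG", v), "does not match ref")
  expect_error(motif_delta(pw, "GGGACGTG", v), "odd length")
  expect_error(motif_delta(pw, "GACGG", sim_variant(ref = "C", alt = "T")),
               "each side")
})

test_that("altered is monotone in |delta| for a fixed threshold", {
  pw <- consensus_pwm("ACGT")
  v <- sim_variant(ref = "G", alt = "C")
  d <- motif_delta(pw, "TTACGTTTT", v, threshold = 1.0)
  strict <- motif_delta(pw, "TTACGTTTT", v, threshold = abs(d$delta) + 1)
  expect_true(d$altered)
  expect_false(strict$altered)
})

test_that("PWM file parsing round-trips probabilities and renormalizes", {
  f <- tempfile(fileext = ".pwm")
  writeLines(c(">FOXA2", "0.97 0.01 0.01 0.01", "0.01 0.97 0.01 0.01",
               "0.01 0.01 0.97 0.01", "0.01 0.01 0.01 0.97",
               ">SOX2", "0.25 0.25 0.25 0.25", "0.25 0.25 0.25 0.25",
               "0.1 0.2 0.3 0.4", "0.4 0.3 0.2 0.1"), f)
  pwms <- read_pwm(f, pseudocount = 0.01)
  expect_named(pwms, c("FOXA2", "SOX2"))
  expect_equal(nrow(pwms$FOXA2$probs), 4L)
  expect_true(all(abs(rowSums(pwms$SOX2$probs) - 1) < 1e-9))
})

test_that("TF-identity matching is case-insensitive and alias-aware", {
  expect_true(is_matched("POLR2A", c("POLR2A")))
  expect_true(is_matched("polr2a", c("POLR2A")))
  expect_false(is_matched("CTCF", c("POLR2A")))
  expect_false(is_matched("ANY", character()))
  amap <- read_alias_map()
  expect_true(is_matched("HNF3beta", c("FOXA2", "EP300"), amap))
  expect_false(is_matched("HNF3beta", c("EP300"), amap))
})
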