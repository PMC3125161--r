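cfg <- pd_config()

test_that("initial score matrix: self-similarity and SSE contribution", {
  d <- toy_domain_of_length(40, seed = 1)
  S <- init_score_matrix(d, d)
  # diagonal entries are row maxima (identical environments)
  for (i in seq_len(d$n)) expect_equal(S[i, i], max(S[i, ]))
  expect_equal(S, t(S), tolerance = 1e-12)
  # entries live in the rescore range
  expect_true(all(S >= -cfg$kappa - 1e-12 & S <= 1 - cfg$kappa + 1e-12))
  # an SSE mismatch removes exactly the w_sse term
  h <- ca_structure(make_helix(15), sse = rep("H", 15))
  h_as_c <- ca_structure(make_helix(15), sse = rep("C", 15))
  expect_equal(init_score_matrix(h, h) - init_score_matrix(h, h_as_c),
               matrix(cfg$w_sse, 15, 15), tolerance = 1e-12)
  expect_error(init_score_matrix(ca_structure(make_helix(8)), h),
               "assign_sse")
})

test_that("dp_align handles the worked degenerate and trivial cases", {
  r <- dp_align(matrix(1, 6, 6), penalty = 0)
  expect_equal(nrow(r$pairs), 6L)
  expect_equal(r$pairs, cbind(1:6, 1:6))
  expect_equal(r$objective, 6)
  # min-block unreachable: empty alignment is a valid result
  r5 <- dp_align(matrix(5, 5, 5), penalty = 0.3)
  expect_equal(nrow(r5$pairs), 0L)
  expect_equal(r5$objective, -0.3 * 10)
})

test_that("dp_align equals the brute-force enumerator on random matrices", {
  set.seed(101)
  for (rep in 1:40) {
    n1 <- sample(6:11, 1); n2 <- sample(6:11, 1)
    S <- matrix(rnorm(n1 * n2, mean = 0.05, sd = 0.4), n1, n2)
    p <- sample(c(0, 0.0622, 0.15), 1)
    r <- dp_align(S, p)
    expect_equal(r$objective, bf_block_align(S, p), tolerance = 1e-10)
    # returned pairs must themselves achieve the reported objective
    expect_equal(alignment_objective(S, r$pairs, p), r$objective,
                 tolerance = 1e-10)
  }
})

test_that("dp_align output always satisfies the alignment invariants", {
  set.seed(55)
  for (rep in 1:25) {
    S <- matrix(rnorm(20 * 17, mean = 0.1, sd = 0.5), 20, 17)
    r <- dp_align(S, 0.0622)
    p <- r$pairs
    if (nrow(p) == 0) next
    expect_true(all(diff(p[, 1]) > 0) && all(diff(p[, 2]) > 0))
    # maximal diagonal runs all have length >= 6
    is_start <- c(TRUE, diff(p[, 1]) != 1 | diff(p[, 2]) != 1)
    expect_true(all(rle(cumsum(is_start))$lengths >= 6))
  }
})

test_that("objective-form identity holds exactly on random alignments", {
  set.seed(202)
  for (rep in 1:50) {
    n1 <- sample(12:30, 1); n2 <- sample(12:30, 1)
    S <- matrix(rnorm(n1 * n2), n1, n2)
    p <- runif(1, 0, 0.3)
    # a random (not necessarily optimal) single-block alignment
    k <- sample(6:min(n1, n2), 1)
    i0 <- sample(seq_len(n1 - k + 1), 1); j0 <- sample(seq_len(n2 - k + 1), 1)
    pairs <- cbind(i0:(i0 + k - 1), j0:(j0 + k - 1))
    f_eq1 <- alignment_objective(S, pairs, p)
    f_gain <- sum(S[pairs] + 2 * p) - p * (n1 + n2)
    expect_equal(f_eq1, f_gain, tolerance = 1e-12)
  }
})

test_that("rescore reproduces the distance-score calibration", {
  d <- toy_domain_of_length(30, seed = 2)
  fs <- structure_fragments(d, m = cfg$m)
  pairs <- cbind(1:d$n, 1:d$n)
  tr <- compute_local_transforms(d, d, pairs, fs, fs)
  S <- rescore(d, d, pairs, tr, fs, fs, cfg)
  # d = 0 on the diagonal: S = 1 - kappa
  expect_equal(diag(S), rep(1 - cfg$kappa, d$n), tolerance = 1e-8)
  expect_true(all(S >= -cfg$kappa - 1e-12))
  # break-even at 9 A: the net gain of a matched pair vanishes exactly
  s9 <- 1 / (1 + 81 / cfg$d0) - cfg$kappa
  expect_equal(s9 + 2 * cfg$penalty, 0, tolerance = 1e-12)
})

test_that("local transforms recover the hinge ground truth", {
  d <- toy_four_helix(seed = 14)
  n <- d$n
  hinge <- 33L
  hp <- make_hinge_pair(d, hinge_site = hinge, angle = 60, axis_seed = 9)
  small <- pd_config(m = 10)   # confine neighbourhoods within a half
  fa <- structure_fragments(hp$a, m = small$m)
  fb <- structure_fragments(hp$b, m = small$m)
  pairs <- cbind(1:n, 1:n)
  tr <- compute_local_transforms(hp$a, hp$b, pairs, fa, fb)
  # fragment pairs well inside the N-half carry the identity
  frags <- fa$fragments
  nhalf <- which(frags$end <= hinge - 12L)
  chalf <- which(frags$start >= hinge + 12L)
  expect_gt(length(nhalf), 0); expect_gt(length(chalf), 0)
  for (fi in nhalf) {
    t_id <- tr[[paste0(fi, ":", fi)]]
    expect_true(is_defined(t_id))
    expect_lt(max(abs(t_id$rotation - diag(3))), 1e-6)
    expect_lt(max(abs(t_id$translation)), 1e-6)
  }
  # fragment pairs inside the C-half all carry one common rotation (the
  # applied hinge motion), which is not the identity
  rots <- lapply(chalf, function(fi) tr[[paste0(fi, ":", fi)]]$rotation)
  for (R in rots) expect_lt(max(abs(R - rots[[1]])), 1e-6)
  expect_gt(max(abs(rots[[1]] - diag(3))), 0.1)
})

test_that("undefined local transforms arise below three pairs", {
  d <- toy_domain_of_length(30, seed = 5)
  fs <- structure_fragments(d, m = 6)
  pairs <- cbind(c(1L, 2L), c(1L, 2L))
  tr <- compute_local_transforms(d, d, pairs, fs, fs)
  expect_true(length(tr) >= 1)
  expect_false(any(vapply(tr, is_defined, logical(1))))
})

test_that("self-alignment scores exactly 1 with full-length matching", {
  d <- toy_four_helix(seed = 3)
  r <- pd_align(d, d)
  expect_identical(r$pd_score, 1)
  expect_equal(nrow(r$pairs), d$n)
  expect_equal(r$pairs, cbind(1:d$n, 1:d$n))
  expect_true(all(abs(r$distances) < 1e-8))
  expect_true(r$converged)
})

test_that("pd_align is exactly symmetric under argument swap", {
  a <- toy_domain_of_length(45, seed = 21)
  b <- toy_domain_of_length(60, seed = 22)
  r1 <- pd_align(a, b)
  r2 <- pd_align(b, a)
  expect_identical(r1$pd_score, r2$pd_score)
  expect_identical(r1$pairs, r2$pairs[, c(2, 1), drop = FALSE])
  expect_identical(r1$iterations, r2$iterations)
})

test_that("pd_align is deterministic across repeated runs", {
  a <- toy_domain_of_length(40, seed = 31)
  b <- toy_domain_of_length(50, seed = 32)
  r1 <- pd_align(a, b)
  r2 <- pd_align(a, b)
  expect_identical(r1$pairs, r2$pairs)
  expect_identical(r1$pd_score, r2$pd_score)
})

test_that("structures shorter than the block size give an empty result", {
  tiny <- assign_sse(make_domain(list(helix = 4), seed = 1))
  big <- toy_domain_of_length(30, seed = 2)
  r <- pd_align(tiny, big)
  expect_equal(nrow(r$pairs), 0L)
  expect_identical(r$pd_score, 0)
})

test_that("worked PD-score example: 6 exact pairs out of 10 score 0.6", {
  d <- toy_domain_of_length(10, seed = 7)
  fs <- structure_fragments(d, m = cfg$m)
  pairs <- cbind(1:6, 1:6)
  tr <- compute_local_transforms(d, d, pairs, fs, fs)
  sc <- pd_score_pairs(d, d, pairs, tr, fs, fs, cfg)
  expect_equal(sc$pd_score, 0.6, tolerance = 1e-10)
  # empty alignment scores 0
  sc0 <- pd_score_pairs(d, d, matrix(integer(0), 0, 2), list(), fs, fs, cfg)
  expect_identical(sc0$pd_score, 0)
})

test_that("evaluate_alignment: identity, degradation, consistency", {
  d <- toy_four_helix(seed = 18)
  idp <- cbind(1:d$n, 1:d$n)
  expect_equal(evaluate_alignment(d, d, idp)$pd_score, 1)
  # monotone degradation with coordinate noise
  jig <- function(sig, seed) {
    dj <- make_domain(list(
      list(kind = "helix", length = 14), list(kind = "loop", length = 3),
      list(kind = "helix", length = 14), list(kind = "loop", length = 3),
      list(kind = "helix", length = 14), list(kind = "loop", length = 3),
      list(kind = "helix", length = 14)), seed = 18, jitter = sig)
    dj$sse <- d$sse
    evaluate_alignment(d, dj, idp)$pd_score
  }
  s05 <- jig(0.5); s5 <- jig(5)
  expect_lt(s05, 1); expect_gt(s05, s5)
  # consistency with the optimiser's own score
  b <- make_hinge_pair(d, 33L, 70, axis_seed = 4)$b
  r <- pd_align(d, b)
  expect_equal(evaluate_alignment(d, b, r$pairs)$pd_score, r$pd_score,
               tolerance = 1e-12)
  # non-monotone pairs are rejected
  expect_error(evaluate_alignment(d, d, cbind(c(2, 1), c(1, 2))),
               "increasing")
})

test_that("pd_score degrades monotonically with noise (trend over seeds)", {
  worse <- 0
  for (seed in 1:10) {
    d <- toy_domain_of_length(50, seed = seed + 100)
    idp <- cbind(1:d$n, 1:d$n)
    sc <- vapply(c(0.3, 1.5, 4), function(sig) {
      dj <- d
      set.seed(seed)
      dj$xyz <- d$xyz + matrix(rnorm(3 * d$n, sd = sig), ncol = 3)
      evaluate_alignment(d, dj, idp)$pd_score
    }, numeric(1))
    if (all(diff(sc) < 0)) worse <- worse + 1
  }
  expect_gte(worse, 9)
})
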