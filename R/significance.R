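# Score statistics: EVD fits, context-tagged P-values, priors, Bayesian
# posteriors, phase-transition thresholds, error curves, length
# regressions.

.default_grid <- function() seq(0, 1, by = 0.001)

#' Maximum-likelihood Gumbel (EVD type I) fit
#'
#' Fits the right-skewed Gumbel distribution
#' `F(x) = exp(-exp(-(x - location) / scale))` by maximum likelihood
#' (moment estimates as the starting point).  A goodness measure
#' `fit_r2` is reported: the coefficient of determination of expected vs
#' observed bin frequencies at bin width `bin`.
#'
#' @param scores numeric vector (at least 100 values; constant input is
#'   an error).
#' @param bin histogram bin width for `fit_r2` (default 0.005).
#' @return Object of class `gumbel_fit` with `location`, `scale`,
#'   `fit_r2`, `n`, `method`.
#' @export
fit_gumbel <- function(scores, bin = 0.005) {
  scores <- as.numeric(scores)
  stopifnot(all(is.finite(scores)))
  if (length(scores) < 100L) stop("need at least 100 scores for an EVD fit")
  if (stats::sd(scores) == 0) stop("degenerate (constant) score sample")
  # centre the data first: the fit is then exactly shift-equivariant
  ctr <- mean(scores)
  x <- scores - ctr
  beta0 <- stats::sd(x) * sqrt(6) / pi
  mu0 <- -0.5772156649 * beta0
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (x - mu) / beta
    length(x) * log(beta) + sum(z) + sum(exp(-z))
  }
  opt <- stats::optim(c(mu0, log(beta0)), nll, method = "BFGS",
                      control = list(reltol = 1e-12, maxit = 500))
  mu <- opt$par[1] + ctr; beta <- exp(opt$par[2])

  # expected vs observed frequencies on a common binning
  breaks <- seq(floor(min(scores) / bin) * bin,
                ceiling(max(scores) / bin) * bin + bin, by = bin)
  obs <- graphics::hist(scores, breaks = breaks, plot = FALSE)$counts
  cdf <- exp(-exp(-(breaks - mu) / beta))
  expc <- length(scores) * diff(cdf)
  r2 <- 1 - sum((obs - expc)^2) / sum((obs - mean(obs))^2)

  structure(list(location = mu, scale = beta, fit_r2 = r2,
                 n = length(scores), method = "mle"),
            class = "gumbel_fit")
}

#' @param x a `gumbel_fit`.
#' @param ... ignored.
#' @rdname fit_gumbel
#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("<gumbel_fit: location %.4f, scale %.4f, R2 %.4f, n %d>\n",
              x$location, x$scale, x$fit_r2, x$n))
  invisible(x)
}

#' Gumbel survival P-value
#'
#' `P(S >= s) = 1 - exp(-exp(-(s - location) / scale))`.
#'
#' @param fit a [fit_gumbel()] result (or any list with `location`,
#'   `scale`).
#' @param s score(s).
#' @return P-value(s) in [0, 1].
#' @export
gumbel_pvalue <- function(fit, s) {
  stopifnot(fit$scale > 0)
  1 - exp(-exp(-(s - fit$location) / fit$scale))
}

#' Empirical P-value curve from a null score sample
#'
#' The right-continuous empirical survival `P(S >= s)` of the null
#' sample, evaluated on a score grid; 1 at or below the sample minimum,
#' non-increasing throughout.
#'
#' @param null_scores numeric null sample (nonempty).
#' @param grid evaluation grid (default `seq(0, 1, 0.001)`).
#' @param context context tag (`gapless`, `fold`, `homology`).
#' @return Object of class `pvalue_curve` with `grid`, `pvalue`, `n`,
#'   `context`.
#' @export
empirical_pvalue_curve <- function(null_scores, grid = .default_grid(),
                                   context = "gapless") {
  stopifnot(length(null_scores) >= 1L, all(is.finite(null_scores)))
  sv <- sort(as.numeric(null_scores))
  n <- length(sv)
  pv <- (n - findInterval(grid, sv, left.open = TRUE)) / n
  structure(list(grid = grid, pvalue = pv, n = n, context = context),
            class = "pvalue_curve")
}

#' Look up a P-value (or posterior) curve at a score
#'
#' Step-function lookup: the value at the largest grid point not
#' exceeding `s`; scores below the grid return the first value.
#'
#' @param curve a `pvalue_curve` or `posterior_curve`.
#' @param s score(s).
#' @return Curve value(s) at `s`.
#' @export
curve_lookup <- function(curve, s) {
  vals <- if (inherits(curve, "posterior_curve")) curve$posterior
  else curve$pvalue
  idx <- pmax(findInterval(s, curve$grid), 1L)
  vals[idx]
}

#' Prior probability of class co-membership from a two-scheme mapping
#'
#' Over all unordered domain pairs, counts pairs whose domains agree in
#' *both* classification schemes and pairs that disagree in both; the
#' prior is `same / (same + diff)`.  Pairs agreeing in exactly one
#' scheme are excluded from both counts.
#'
#' @param mapping data.frame with columns `domain`, `cath`, `scop` (one
#'   row per domain; at least 2 domains).
#' @return Prior probability in (0, 1].
#' @export
priors_from_mapping <- function(mapping) {
  stopifnot(all(c("cath", "scop") %in% names(mapping)), nrow(mapping) >= 2L)
  n <- nrow(mapping)
  choose2 <- function(k) k * (k - 1) / 2
  total <- choose2(n)
  same_cath <- sum(choose2(table(mapping$cath)))
  same_scop <- sum(choose2(table(mapping$scop)))
  same_both <- sum(choose2(table(paste(mapping$cath, mapping$scop,
                                       sep = "\r"))))
  diff_both <- total - same_cath - same_scop + same_both
  den <- same_both + diff_both
  if (den == 0) stop("no pairs agree or disagree in both schemes: ",
                     "prior undefined")
  same_both / den
}

#' Bayesian posterior curve of class co-membership given a score
#'
#' Per score bin (width `bin`, add-one smoothed densities),
#' `P(same | s) = f_same(s) pi / (f_same(s) pi + f_diff(s) (1 - pi))`.
#' Bins where both raw counts are zero carry no value (`NA`).
#'
#' @param same,diff score samples of same-class and different-class
#'   pairs (nonempty).
#' @param prior_same prior probability of co-membership, in (0, 1).
#' @param bin density bin width (default 0.01).
#' @param grid evaluation grid (default `seq(0, 1, 0.001)`).
#' @param context context tag.
#' @return Object of class `posterior_curve`: `grid`, `posterior`,
#'   `prior`, `context`, plus the samples (`same`, `diff`) for
#'   downstream threshold/error reports.
#' @export
posterior_curve <- function(same, diff, prior_same, bin = 0.01,
                            grid = .default_grid(), context = "fold") {
  stopifnot(length(same) >= 1L, length(diff) >= 1L,
            prior_same > 0, prior_same < 1)
  lo <- floor(min(same, diff, 0) / bin) * bin
  hi <- ceiling(max(same, diff, 1) / bin) * bin
  breaks <- seq(lo, hi, by = bin)
  cs <- graphics::hist(same, breaks = breaks, plot = FALSE)$counts
  cd <- graphics::hist(diff, breaks = breaks, plot = FALSE)$counts
  nb <- length(cs)
  fs <- (cs + 1) / (length(same) + nb)     # Laplace-smoothed densities
  fd <- (cd + 1) / (length(diff) + nb)
  post <- fs * prior_same / (fs * prior_same + fd * (1 - prior_same))
  post[cs == 0 & cd == 0] <- NA_real_
  idx <- pmin(pmax(findInterval(grid, breaks, rightmost.closed = TRUE), 1L),
              nb)
  structure(list(grid = grid, posterior = post[idx], prior = prior_same,
                 bin = bin, context = context,
                 same = as.numeric(same), diff = as.numeric(diff)),
            class = "posterior_curve")
}

#' Phase-transition threshold of a posterior curve
#'
#' The smallest grid score at which the posterior reaches 0.5 and stays
#' at or above 0.5 for the next `k` populated grid points (an anti-noise
#' guard for small samples).  The report includes the a priori errors at
#' the threshold (type I = empirical P-value of the threshold on the
#' different-class sample; type II = `P(S < s* | same)`) and the
#' prior-weighted a posteriori errors `P(diff | S >= s*)` and
#' `P(same | S < s*)`.
#'
#' @param curve a [posterior_curve()].
#' @param k stability window in populated grid points (default 5).
#' @return Object of class `threshold_report` with `threshold`,
#'   `posterior_at_threshold`, `type_I`, `type_II`,
#'   `posterior_error_above`, `posterior_error_below`, `context`.
#' @export
phase_threshold <- function(curve, k = 5L) {
  stopifnot(inherits(curve, "posterior_curve"))
  ok <- which(!is.na(curve$posterior))
  vals <- curve$posterior[ok]
  if (vals[1] >= 0.5)
    stop("no 0.5 upcrossing: posterior already at/above 0.5 at the low ",
         "score end (no phase transition)")
  hit <- NA_integer_
  for (t in seq_along(vals)) {
    up <- t:min(t + k, length(vals))
    if (all(vals[up] >= 0.5)) { hit <- t; break }
  }
  if (is.na(hit))
    stop("no stable 0.5 upcrossing in posterior curve (values span ",
         sprintf("%.3f..%.3f", min(vals), max(vals)), ")")
  s_star <- curve$grid[ok[hit]]
  same <- curve$same; diff <- curve$diff; pri <- curve$prior
  p_ge_s_same <- mean(same >= s_star)
  p_ge_s_diff <- mean(diff >= s_star)
  num_above <- p_ge_s_diff * (1 - pri)
  den_above <- num_above + p_ge_s_same * pri
  num_below <- (1 - p_ge_s_same) * pri
  den_below <- num_below + (1 - p_ge_s_diff) * (1 - pri)
  structure(list(
    threshold = s_star,
    posterior_at_threshold = vals[hit],
    type_I = p_ge_s_diff,
    type_II = 1 - p_ge_s_same,
    posterior_error_above = if (den_above > 0) num_above / den_above else NA,
    posterior_error_below = if (den_below > 0) num_below / den_below else NA,
    context = curve$context), class = "threshold_report")
}

#' @param x a `threshold_report`.
#' @param ... ignored.
#' @rdname phase_threshold
#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<threshold_report [%s]: s* = %.3f, posterior %.3f,\n",
    "  type I %.6f, type II %.6f, P(diff|S>=s*) %.4f, P(same|S<s*) %.4f>\n"),
    x$context, x$threshold, x$posterior_at_threshold,
    x$type_I, x$type_II, x$posterior_error_above, x$posterior_error_below))
  invisible(x)
}

#' Type I / type II error curve over score thresholds
#'
#' For each threshold `t`: type I = `P(S >= t | diff)`, type II =
#' `P(S < t | same)`.  Type I is non-increasing and type II
#' non-decreasing in `t`; thresholds below (above) all scores give
#' exactly (1, 0) ((0, 1)).
#'
#' @param same,diff score samples (nonempty).
#' @param thresholds threshold grid (default `seq(0, 1, 0.001)`).
#' @return data.frame with columns `threshold`, `type_I`, `type_II`.
#' @export
error_curve <- function(same, diff, thresholds = .default_grid()) {
  stopifnot(length(same) >= 1L, length(diff) >= 1L)
  sd_ <- sort(as.numeric(diff)); ss <- sort(as.numeric(same))
  nd <- length(sd_); ns <- length(ss)
  t1 <- (nd - findInterval(thresholds, sd_, left.open = TRUE)) / nd
  t2 <- findInterval(thresholds, ss, left.open = TRUE) / ns
  data.frame(threshold = thresholds, type_I = t1, type_II = t2)
}

#' Top-hit rate of an all-vs-all score table
#'
#' Fraction of queries whose highest-scoring partner is in the same
#' class; ties are broken by the lexicographically smallest partner id.
#' A rank statistic: invariant under monotone transformations of the
#' scores.
#'
#' @param scores data.frame with columns `query`, `partner`, `score`,
#'   `label` (`same`/`diff`); every query needs at least one partner of
#'   each label.
#' @return Probability in [0, 1].
#' @export
top_hit_rate <- function(scores) {
  stopifnot(all(c("query", "partner", "score", "label") %in% names(scores)))
  qs <- split(scores, scores$query)
  hit <- vapply(qs, function(d) {
    if (!all(c("same", "diff") %in% d$label))
      stop("query ", d$query[1], " lacks a same or diff partner")
    d <- d[order(-d$score, d$partner), ]
    d$label[1] == "same"
  }, logical(1))
  mean(hit)
}

#' Length-dependence regression of mean scores
#'
#' Groups records by the chosen domain length, computes per-length mean
#' scores, and regresses them on length by weighted least squares with
#' the per-length record counts as weights (so frequent lengths drive
#' the fit).  `high_only` first filters records to `score > high_only`,
#' the paper-style restriction to the discriminant score range.
#'
#' @param sample a `score_sample` data.frame (columns `L1`, `L2`,
#'   `score`).
#' @param which_length `"first"` (L1), `"second"` (L2), or `"min"`.
#' @param high_only optional score threshold; records at or below it are
#'   dropped before grouping.
#' @return Object of class `length_regression`: `slope`,
#'   `slope_per_1000`, `adj_r2`, `n_groups`, `which_length`,
#'   `high_only`, `weighted`.
#' @export
length_regression <- function(sample,
                              which_length = c("first", "second", "min"),
                              high_only = NULL) {
  which_length <- match.arg(which_length)
  stopifnot(all(c("L1", "L2", "score") %in% names(sample)))
  L <- switch(which_length, first = sample$L1, second = sample$L2,
              min = pmin(sample$L1, sample$L2))
  sc <- sample$score
  if (!is.null(high_only)) {
    keep <- sc > high_only
    L <- L[keep]; sc <- sc[keep]
  }
  grp <- tapply(sc, L, mean)
  wts <- as.numeric(table(L))
  len <- as.numeric(names(grp))
  if (length(len) < 3L) stop("need at least 3 distinct lengths, got ",
                             length(len))
  if (diff(range(grp)) < 1e-12) {
    # constant per-length means: no dependence, nothing to explain
    slope <- 0; adj_r2 <- 0
  } else {
    fit <- stats::lm(y ~ x, data = data.frame(x = len, y = as.numeric(grp)),
                     weights = wts)
    slope <- unname(stats::coef(fit)[2])
    adj_r2 <- summary(fit)$adj.r.squared
  }
  structure(list(slope = slope,
                 slope_per_1000 = slope * 1000,
                 adj_r2 = adj_r2,
                 n_groups = length(len),
                 which_length = which_length,
                 high_only = high_only,
                 weighted = TRUE), class = "length_regression")
}

#' Symmetrised score of a two-way score table
#'
#' Utility averaging two ingested directional score columns (e.g.
#' TM-score(a, b) and TM-score(b, a)).
#'
#' @param s_ab,s_ba numeric score vectors of equal length.
#' @return Element-wise mean.
#' @export
symmetrize_scores <- function(s_ab, s_ba) {
  stopifnot(length(s_ab) == length(s_ba))
  (s_ab + s_ba) / 2
}

#' Read / write labelled score samples as TSV
#'
#' The interchange format of the significance toolkit: a header line with
#' columns `pair_id`, `L1`, `L2`, `score`, `label`, `context`.
#'
#' @param path file path.
#' @return `read_score_sample`: a `score_sample` data.frame.
#' @export
read_score_sample <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("pair_id", "L1", "L2", "score", "label", "context")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("score TSV missing columns: ",
                         paste(miss, collapse = ", "))
  class(d) <- c("score_sample", "data.frame")
  d
}

#' @param sample a `score_sample`.
#' @rdname read_score_sample
#' @export
write_score_sample <- function(sample, path) {
  utils::write.table(sample, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
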