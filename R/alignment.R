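#' Alignment engine configuration
#'
#' Bundles the tunable constants of the aligner.  The distance-to-score
#' term is `simterm(d^2) = 1 / (1 + d^2 / d0)` with `d0 = 11.5` (A^2);
#' score-matrix entries are `simterm(d^2) - kappa` with
#' `kappa = 2 * simterm(81)`, and the per-site gap penalty defaults to
#' `simterm(81) / 2`.  With these choices the net gain of matching a pair
#' at distance d, `S + 2*penalty = simterm(d^2) - simterm(81)`, is
#' positive exactly when d < 9 A: a pair farther than 9 A apart is a poor
#' alignment pair.
#'
#' @param m fragment neighbourhood size (sites), see
#'   [fragment_neighbourhood()].
#' @param d0 distance softening constant (A^2) of the score term.
#' @param penalty per-unmatched-site penalty of the DP objective.
#' @param min_block minimum diagonal-run length of matched sites.
#' @param max_steps iteration cap of the align loop.
#' @param normalization PD-score length normalisation: `"avg"` uses
#'   `2/(L1+L2)` (symmetric, default), `"min"` uses `1/min(L1,L2)`,
#'   `"geom"` uses `1/sqrt(L1*L2)`.
#' @param w_sse,w_prof weights of the SSE-match and distance-profile
#'   terms of the initial score matrix (they should sum to 1 so initial
#'   entries span the same range as rescored entries).
#' @param d0_prof softening constant (A^2) of the profile term.
#' @return A list of class `pd_config`.
#' @export
pd_config <- function(m = 40L, d0 = 11.5,
                      penalty = 0.5 / (1 + 81 / d0),
                      min_block = 6L, max_steps = 30L,
                      normalization = c("avg", "min", "geom"),
                      w_sse = 0.5, w_prof = 0.5, d0_prof = 1.0) {
  normalization <- match.arg(normalization)
  stopifnot(m >= 1L, d0 > 0, penalty >= 0, min_block >= 1L, max_steps >= 1L)
  structure(list(m = as.integer(m), d0 = d0, penalty = penalty,
                 min_block = as.integer(min_block),
                 max_steps = as.integer(max_steps),
                 normalization = normalization,
                 w_sse = w_sse, w_prof = w_prof, d0_prof = d0_prof,
                 kappa = 2 / (1 + 81 / d0)),
            class = "pd_config")
}

simterm <- function(d2, d0 = 11.5) 1 / (1 + d2 / d0)

# ---- initial score matrix -------------------------------------------------

#' Initial score matrix from SSE match and local distance profiles
#'
#' Surrogate for the structure-environment classifier used to seed the
#' iteration (the original initialisation tables are not public).  Entry
#' (i, j) combines a secondary-structure match indicator with the
#' similarity of the intra-chain distance profiles d(i, i+k), k in
#' -4..4 (k != 0, clamped at chain ends):
#' `s0 = w_sse * match + w_prof / (1 + delta2 / d0_prof) - kappa`,
#' where `delta2` is the mean squared profile difference over shared
#' offsets.  With `w_sse + w_prof = 1` the entries span the same
#' `[-kappa, 1-kappa]` range as rescored entries.
#'
#' @param a,b [ca_structure()]s with SSE labels assigned.
#' @param cfg a [pd_config()].
#' @return L1 x L2 numeric score matrix.
#' @export
init_score_matrix <- function(a, b, cfg = pd_config()) {
  stopifnot(inherits(a, "ca_structure"), inherits(b, "ca_structure"))
  if (anyNA(a$sse) || anyNA(b$sse))
    stop("SSE labels missing: run assign_sse() on both structures first")
  pa <- distance_profile(a$xyz)
  pb <- distance_profile(b$xyz)
  d2sum <- matrix(0, a$n, b$n)
  cnt <- matrix(0, a$n, b$n)
  for (k in seq_len(ncol(pa))) {
    va <- pa[, k]; vb <- pb[, k]
    ok <- outer(!is.na(va), !is.na(vb), "&")
    dif <- outer(ifelse(is.na(va), 0, va), ifelse(is.na(vb), 0, vb), "-")^2
    d2sum <- d2sum + dif * ok
    cnt <- cnt + ok
  }
  delta2 <- ifelse(cnt > 0, d2sum / pmax(cnt, 1), 0)
  prof <- 1 / (1 + delta2 / cfg$d0_prof)
  sse_match <- outer(a$sse, b$sse, "==") * 1
  cfg$w_sse * sse_match + cfg$w_prof * prof - cfg$kappa
}

# n x 8 matrix of intra-chain CA distances d(i, i+k), k = -4..-1, 1..4
distance_profile <- function(xyz) {
  n <- nrow(xyz)
  ks <- c(-4:-1, 1:4)
  out <- matrix(NA_real_, n, length(ks))
  for (c in seq_along(ks)) {
    k <- ks[c]
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    out[i[ok], c] <- sqrt(rowSums((xyz[i[ok], , drop = FALSE] -
                                     xyz[j[ok], , drop = FALSE])^2))
  }
  out
}

# ---- dynamic programming --------------------------------------------------

#' Block-constrained alignment by dynamic programming
#'
#' Maximises `F = sum_{(i,j) in pi} S(i,j) - penalty * ((L1 - Na) +
#' (L2 - Na))` over order-preserving one-to-one matchings in which every
#' matched site sits in a diagonal run of at least `min_block`
#' consecutive matches (adjacent blocks merge before the length check).
#' Equivalently maximises the per-pair gain `S + 2*penalty` summed over
#' matched pairs, up to the constant `penalty * (L1 + L2)`.
#'
#' @param S L1 x L2 score matrix.
#' @param penalty non-negative per-unmatched-site penalty.
#' @param min_block minimum diagonal-run length (default 6).
#' @return List with `pairs` (Na x 2 integer matrix of 1-based site
#'   indices, strictly increasing in both columns), `gain` and
#'   `objective` (the value of F).  When `min(L1, L2) < min_block` the
#'   empty alignment is returned (a valid result, not an error).
#' @export
dp_align <- function(S, penalty, min_block = 6L) {
  S <- as.matrix(S)
  stopifnot(penalty >= 0, min_block >= 1L, all(is.finite(S)))
  dp_align_cpp(S, penalty, as.integer(min_block))
}

# key used for convergence detection (exact matching identity)
alignment_key <- function(pairs) {
  if (nrow(pairs) == 0L) return("<empty>")
  paste(pairs[, 1], pairs[, 2], sep = ":", collapse = ",")
}

# ---- local transforms and rescoring --------------------------------------

#' Per-fragment-pair local rigid transformations
#'
#' For every fragment pair (F, G) containing at least one aligned pair,
#' the local alignment is the reduction of the matching to the
#' neighbourhoods N_m(F) and N_m(G); its Kabsch superposition is the
#' local transformation of (F, G).  Local alignments with fewer than
#' three pairs yield an *undefined* transformation.
#'
#' @param a,b the two structures.
#' @param pairs Na x 2 matrix of aligned site indices.
#' @param fa,fb fragment/neighbourhood bundles from
#'   [structure_fragments()].
#' @return Named list of [rigid_transform()]s keyed `"<fi>:<gj>"`.
#' @export
compute_local_transforms <- function(a, b, pairs, fa, fb) {
  out <- list()
  if (nrow(pairs) == 0L) return(out)
  fi <- fa$frag_of[pairs[, 1]]
  gj <- fb$frag_of[pairs[, 2]]
  keys <- unique(paste(fi, gj, sep = ":"))
  for (key in keys) {
    kk <- as.integer(strsplit(key, ":")[[1]])
    nbA <- fa$neighbourhoods[[kk[1]]]
    nbB <- fb$neighbourhoods[[kk[2]]]
    sel <- pairs[, 1] %in% nbA & pairs[, 2] %in% nbB
    if (sum(sel) < 3L) {
      out[[key]] <- undefined_transform()
    } else {
      out[[key]] <- kabsch(a$xyz[pairs[sel, 1], , drop = FALSE],
                           b$xyz[pairs[sel, 2], , drop = FALSE])
    }
  }
  out
}

# global fallback transform over the whole current matching
global_transform <- function(a, b, pairs) {
  if (nrow(pairs) < 3L) return(undefined_transform())
  kabsch(a$xyz[pairs[, 1], , drop = FALSE],
         b$xyz[pairs[, 2], , drop = FALSE])
}

#' Distance-based score matrix from the current transforms
#'
#' `S(i, j) = simterm(d^2) - kappa` with
#' `d = || T_{F(i),G(j)}(x_i) - y_j ||`, using the fragment-pair local
#' transformation when defined, the global whole-matching Kabsch
#' transform otherwise, and `S = -kappa` when no transform is available
#' at all.
#'
#' @inheritParams compute_local_transforms
#' @param transforms output of [compute_local_transforms()].
#' @param cfg a [pd_config()].
#' @return L1 x L2 numeric score matrix.
#' @export
rescore <- function(a, b, pairs, transforms, fa, fb, cfg = pd_config()) {
  gt <- global_transform(a, b, pairs)
  if (is_defined(gt)) {
    ta <- transform_coords(gt, a$xyz)
    d2 <- cross_dist2(ta, b$xyz)
    S <- simterm(d2, cfg$d0) - cfg$kappa
  } else {
    S <- matrix(-cfg$kappa, a$n, b$n)
  }
  for (key in names(transforms)) {
    tr <- transforms[[key]]
    if (!is_defined(tr)) next
    kk <- as.integer(strsplit(key, ":")[[1]])
    ra <- fa$fragments$start[kk[1]]:fa$fragments$end[kk[1]]
    rb <- fb$fragments$start[kk[2]]:fb$fragments$end[kk[2]]
    ta <- transform_coords(tr, a$xyz[ra, , drop = FALSE])
    d2 <- cross_dist2(ta, b$xyz[rb, , drop = FALSE])
    S[ra, rb] <- simterm(d2, cfg$d0) - cfg$kappa
  }
  S
}

# squared Euclidean cross-distance matrix between row sets
cross_dist2 <- function(P, Q) {
  d2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  pmax(d2, 0)
}

# ---- PD-score -------------------------------------------------------------

# normalising denominator; PD = sum(simterm) / denom.  Dividing (rather
# than multiplying by a reciprocal) keeps the self-alignment score exactly 1.
norm_denom <- function(L1, L2, normalization) {
  switch(normalization,
         avg = (L1 + L2) / 2,
         min = min(L1, L2),
         geom = sqrt(as.numeric(L1) * L2))
}

#' PD-score of a matching under fragment-local transformations
#'
#' `PD = (2 / (L1 + L2)) * sum_{(i,j) in pi} simterm(d_ij^2)` by default,
#' where `d_ij` is the distance between the transformed site `x_i` (via
#' the fragment-pair transform of `(F(i), G(j))`, or the global fallback)
#' and `y_j`.  Bounded in [0, 1]; the self-alignment of any structure
#' scores exactly 1.
#'
#' @inheritParams rescore
#' @return List with `pd_score` and per-pair `distances` (A).
#' @export
pd_score_pairs <- function(a, b, pairs, transforms, fa, fb,
                           cfg = pd_config()) {
  L1 <- a$n; L2 <- b$n
  if (nrow(pairs) == 0L)
    return(list(pd_score = 0, distances = numeric(0)))
  gt <- global_transform(a, b, pairs)
  fi <- fa$frag_of[pairs[, 1]]
  gj <- fb$frag_of[pairs[, 2]]
  keys <- paste(fi, gj, sep = ":")
  d <- rep(NA_real_, nrow(pairs))
  for (t in seq_len(nrow(pairs))) {
    tr <- transforms[[keys[t]]]
    if (is.null(tr) || !is_defined(tr)) tr <- gt
    if (!is_defined(tr)) next
    p <- transform_coords(tr, a$xyz[pairs[t, 1], , drop = FALSE])
    d[t] <- sqrt(sum((p - b$xyz[pairs[t, 2], , drop = FALSE])^2))
  }
  contrib <- ifelse(is.na(d), 0, simterm(d^2, cfg$d0))
  list(pd_score = sum(contrib) / norm_denom(L1, L2, cfg$normalization),
       distances = d)
}

# ---- the main iteration ---------------------------------------------------

#' Flexible pairwise structure alignment
#'
#' The iterated algorithm: initialise a score matrix from SSE and
#' distance-profile compatibility, find a block-constrained matching by
#' dynamic programming, fit per-fragment-pair local rigid
#' transformations over fragment neighbourhoods, rescore from the
#' transformed distances, and repeat until the matching repeats the
#' previous one (convergence), a previously seen matching recurs (a
#' cycle; the best-scoring matching seen is kept), or `max_steps` is
#' reached.  Arguments are ordered canonically inside (shorter structure
#' first, ties by id), so the result is exactly symmetric under argument
#' swap.
#'
#' @param a,b [ca_structure()]s with SSE labels (run [assign_sse()]
#'   first).
#' @param cfg a [pd_config()].
#' @return An object of class `pd_alignment`: `pairs` (site indices into
#'   `a` and `b` as passed), `pd_score`, `distances`, `transforms`,
#'   `iterations`, `converged`, `config`.
#' @export
#' @examples
#' d <- assign_sse(make_domain(list(helix = 30), seed = 7))
#' r <- pd_align(d, d)
#' r$pd_score  # exactly 1
pd_align <- function(a, b, cfg = pd_config()) {
  stopifnot(inherits(a, "ca_structure"), inherits(b, "ca_structure"))
  swapped <- (b$n < a$n) || (b$n == a$n && b$id < a$id)
  if (swapped) { tmp <- a; a <- b; b <- tmp }

  empty <- structure(list(pairs = matrix(integer(0), 0, 2),
                          pd_score = 0, distances = numeric(0),
                          transforms = list(), iterations = 0L,
                          converged = TRUE, stopped = "degenerate",
                          config = cfg, id_a = a$id, id_b = b$id),
                     class = "pd_alignment")
  if (min(a$n, b$n) < cfg$min_block) {
    return(finish_alignment(empty, swapped))
  }

  fa <- structure_fragments(a, m = cfg$m)
  fb <- structure_fragments(b, m = cfg$m)
  S <- init_score_matrix(a, b, cfg)

  seen <- character(0)
  prev_key <- NULL
  best <- NULL
  converged <- FALSE
  stopped <- "max_steps"
  iterations <- 0L

  for (step in seq_len(cfg$max_steps)) {
    iterations <- step
    al <- dp_align(S, cfg$penalty, cfg$min_block)
    key <- alignment_key(al$pairs)
    tr <- compute_local_transforms(a, b, al$pairs, fa, fb)
    sc <- pd_score_pairs(a, b, al$pairs, tr, fa, fb, cfg)
    if (is.null(best) || sc$pd_score > best$pd_score) {
      best <- list(pairs = al$pairs, pd_score = sc$pd_score,
                   distances = sc$distances, transforms = tr)
    }
    if (!is.null(prev_key) && key == prev_key) {
      converged <- TRUE; stopped <- "converged"; break
    }
    if (key %in% seen) {
      converged <- TRUE; stopped <- "cycle"; break
    }
    seen <- c(seen, key)
    prev_key <- key
    S <- rescore(a, b, al$pairs, tr, fa, fb, cfg)
  }

  res <- structure(list(pairs = best$pairs, pd_score = best$pd_score,
                        distances = best$distances,
                        transforms = best$transforms,
                        iterations = iterations, converged = converged,
                        stopped = stopped, config = cfg,
                        id_a = a$id, id_b = b$id),
                   class = "pd_alignment")
  finish_alignment(res, swapped)
}

finish_alignment <- function(res, swapped) {
  res$swapped <- swapped
  if (swapped && nrow(res$pairs)) {
    res$pairs <- res$pairs[, c(2, 1), drop = FALSE]
    ids <- res$id_a; res$id_a <- res$id_b; res$id_b <- ids
  } else if (swapped) {
    ids <- res$id_a; res$id_a <- res$id_b; res$id_b <- ids
  }
  res
}

#' @param x a `pd_alignment`.
#' @param ... ignored.
#' @rdname pd_align
#' @export
print.pd_alignment <- function(x, ...) {
  cat(sprintf(
    "<pd_alignment %s vs %s: %d pairs, PD-score %.4f, %d iteration(s), %s>\n",
    x$id_a, x$id_b, nrow(x$pairs), x$pd_score, x$iterations, x$stopped))
  invisible(x)
}

#' Score a fixed, externally supplied alignment
#'
#' Evaluates the PD-score of a given residue correspondence with no
#' optimisation: fragments, neighbourhoods and per-fragment-pair
#' transformations are computed from the supplied pairs only.  This is
#' the evaluation mode used for model-vs-native identity alignments; the
#' minimum-block constraint of the optimiser is *not* enforced here.
#'
#' @param a,b [ca_structure()]s with SSE labels.
#' @param pairs Na x 2 matrix of 1-based site indices, strictly
#'   increasing in both columns.
#' @param cfg a [pd_config()].
#' @return List with `pd_score`, per-pair `distances`, `transforms`.
#' @export
evaluate_alignment <- function(a, b, pairs, cfg = pd_config()) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs)) {
    stopifnot(ncol(pairs) == 2L)
    if (nrow(pairs) > 1L &&
        (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0)))
      stop("pairs must be strictly increasing in both coordinates")
    stopifnot(min(pairs) >= 1L, max(pairs[, 1]) <= a$n,
              max(pairs[, 2]) <= b$n)
  }
  fa <- structure_fragments(a, m = cfg$m)
  fb <- structure_fragments(b, m = cfg$m)
  tr <- compute_local_transforms(a, b, pairs, fa, fb)
  sc <- pd_score_pairs(a, b, pairs, tr, fa, fb, cfg)
  list(pd_score = sc$pd_score, distances = sc$distances, transforms = tr)
}
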