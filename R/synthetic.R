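# Synthetic ideal-geometry structures and simulated score samples.
# These are text-book toy fixtures: every other module is testable with
# no external data.

# run code under a temporarily seeded RNG, restoring global state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Ideal alpha-helix C-alpha trace
#'
#' Points on a helix with rise 1.5 A/residue, radius 2.3 A and 100
#' degrees/residue, giving the canonical ~3.8 A consecutive C-alpha
#' spacing.
#'
#' @param n number of residues (>= 1).
#' @return n x 3 coordinate matrix.
#' @export
make_helix <- function(n) {
  stopifnot(n >= 1L)
  t <- seq_len(n) - 1L
  a <- t * 100 * pi / 180
  cbind(2.3 * cos(a), 2.3 * sin(a), 1.5 * t)
}

#' Ideal extended-strand (zig-zag) C-alpha trace
#'
#' A planar zig-zag with exact 3.8 A consecutive spacing and ~6.6 A
#' d(i,i+2), emulating an extended beta-strand.
#'
#' @param n number of residues (>= 1).
#' @return n x 3 coordinate matrix.
#' @export
make_strand <- function(n) {
  stopifnot(n >= 1L)
  t <- seq_len(n) - 1L
  h <- sqrt(3.8^2 - 3.3^2) / 2        # half zig-zag amplitude
  cbind(3.3 * t, h * (-1)^t, rep(0, n))
}

# gently curved coil segment: 3.8 A steps with seeded direction wander
make_loop <- function(n) {
  stopifnot(n >= 1L)
  pts <- matrix(0, n, 3L)
  dir <- c(1, 0, 0)
  for (i in seq_len(n)[-1]) {
    dir <- dir + stats::rnorm(3, sd = 0.6)
    dir <- dir / sqrt(sum(dir^2))
    pts[i, ] <- pts[i - 1L, ] + 3.8 * dir
  }
  pts
}

#' Build a synthetic multi-segment domain
#'
#' Segments (helix / strand / loop) of given lengths are generated with
#' ideal geometry and placed sequentially: each segment is rotated by a
#' seeded random rotation and attached 3.8 A from the previous segment's
#' last site, retrying (up to `max_retry` times) until no two
#' non-consecutive sites come closer than 3.0 A.  SSE labels are set from
#' the segment kinds.  Optional Gaussian jitter perturbs the final
#' coordinates.
#'
#' @param segments list of `list(kind, length)` entries, kind in
#'   `{"helix","strand","loop"}`; or a compact spec like
#'   `list(helix = 12, loop = 3, helix = 12)`.
#' @param seed integer seed; the same seed reproduces the structure
#'   exactly.
#' @param jitter standard deviation (A) of optional coordinate noise.
#' @param id structure id.
#' @param max_retry placement retries before giving up.
#' @return A [ca_structure()] with SSE labels filled.
#' @export
#' @examples
#' d <- make_domain(list(helix = 20), seed = 1)
#' table(d$sse)  # all H
make_domain <- function(segments, seed = 1L, jitter = 0, id = "synthetic",
                        max_retry = 200L) {
  segments <- normalize_segments(segments)
  stopifnot(length(segments) >= 1L)
  with_seed(seed, {
    xyz <- NULL
    sse <- character(0)
    for (seg in segments) {
      kind <- seg$kind; len <- seg$length
      stopifnot(len >= 1L)
      lab <- switch(kind, helix = "H", strand = "E", loop = "C",
                    stop("unknown segment kind: ", kind))
      for (try in seq_len(max_retry)) {
        base <- switch(kind,
                       helix = make_helix(len),
                       strand = make_strand(len),
                       loop = make_loop(len))
        R <- random_rotation()
        seg_xyz <- base %*% t(R)
        if (is.null(xyz)) {
          cand <- seg_xyz
          ok <- min_self_dist_ok(cand)
        } else {
          dir <- stats::rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          anchor <- xyz[nrow(xyz), ] + 3.8 * dir
          cand <- sweep(seg_xyz, 2L, seg_xyz[1L, ] - anchor, "-")
          ok <- placement_ok(xyz, cand)
        }
        if (ok) break
        if (try == max_retry) stop("segment placement failed after ",
                                   max_retry, " retries")
      }
      xyz <- rbind(xyz, cand)
      sse <- c(sse, rep(lab, len))
    }
    if (jitter > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = jitter),
                                        ncol = 3L)
    ca_structure(xyz, id = id, sse = sse)
  })
}

normalize_segments <- function(segments) {
  out <- list()
  nm <- names(segments)
  for (i in seq_along(segments)) {
    el <- segments[[i]]
    if (is.list(el)) out[[i]] <- el
    else out[[i]] <- list(kind = nm[i], length = as.integer(el))
  }
  out
}

min_self_dist_ok <- function(xyz, min_dist = 3.0) {
  n <- nrow(xyz)
  if (n < 3L) return(TRUE)
  d <- as.matrix(stats::dist(xyz))
  d[abs(row(d) - col(d)) <= 1L] <- Inf
  min(d) >= min_dist
}

placement_ok <- function(old, new, min_dist = 3.0) {
  # new segment internally OK by construction except loops; check cross
  if (!min_self_dist_ok(new, min_dist)) return(FALSE)
  cross <- outer(rowSums(old^2), rowSums(new^2), "+") -
    2 * old %*% t(new)
  # consecutive link between chain end and segment start is allowed
  cross[nrow(old), 1L] <- Inf
  min(cross) >= min_dist^2
}

#' Hinge-rotated structure pair
#'
#' Returns a structure and a copy in which all sites at or beyond
#' `hinge_site` are rigidly rotated about a seeded random axis through
#' the hinge C-alpha.  Residue correspondence between the two is the
#' identity, so the pair is a ground-truth case for flexible alignment.
#'
#' @param s a [ca_structure()] (e.g. from [make_domain()]).
#' @param hinge_site 1-based site index, strictly inside the chain.
#' @param angle rotation angle in degrees.
#' @param axis_seed seed for the random rotation axis.
#' @return List of two [ca_structure()]s, `a` (original) and `b`
#'   (hinge-rotated).
#' @export
make_hinge_pair <- function(s, hinge_site, angle, axis_seed = 1L) {
  stopifnot(inherits(s, "ca_structure"),
            hinge_site > 1L, hinge_site < s$n)
  b <- s
  with_seed(axis_seed, {
    ax <- stats::rnorm(3)
    R <- rotation_about_axis(ax, angle * pi / 180)
    pivot <- s$xyz[hinge_site, ]
    idx <- hinge_site:s$n
    moved <- sweep(sweep(s$xyz[idx, , drop = FALSE], 2L, pivot) %*% t(R),
                   2L, pivot, "+")
    b$xyz[idx, ] <- moved
  })
  b$id <- paste0(s$id, "_hinge")
  list(a = s, b = b)
}

#' Simulate a labelled score sample
#'
#' Emulates the two score populations seen in fold/homology benchmarks:
#' different-class pair scores follow a Gumbel (EVD) law, same-class pair
#' scores a Normal law; both are truncated to (0, 1) by resampling.
#' Lengths are drawn uniformly from `length_range`.
#'
#' @param n_same,n_diff sample sizes.
#' @param diff_mu,diff_beta Gumbel location and scale of the
#'   different-class population.
#' @param same_mean,same_sd Normal mean and sd of the same-class
#'   population.
#' @param context context tag stored on every record.
#' @param length_range integer range for the simulated domain lengths.
#' @param seed integer seed.
#' @return A `score_sample` data.frame with columns `pair_id`, `L1`,
#'   `L2`, `score`, `label` (`same`/`diff`), `context`.
#' @export
sample_scores <- function(n_same, n_diff,
                          diff_mu = 0.058, diff_beta = 0.027,
                          same_mean = 0.5, same_sd = 0.12,
                          context = c("fold", "homology", "gapless"),
                          length_range = c(50L, 300L), seed = 1L) {
  stopifnot(n_same >= 1L, n_diff >= 1L, diff_beta > 0, same_sd > 0)
  context <- match.arg(context)
  with_seed(seed, {
    rs <- truncated_draw(n_same, function(k)
      stats::rnorm(k, same_mean, same_sd))
    rd <- truncated_draw(n_diff, function(k)
      diff_mu - diff_beta * log(-log(stats::runif(k))))
    n <- n_same + n_diff
    out <- data.frame(
      pair_id = sprintf("pair%06d", seq_len(n)),
      L1 = sample(length_range[1]:length_range[2], n, replace = TRUE),
      L2 = sample(length_range[1]:length_range[2], n, replace = TRUE),
      score = c(rs, rd),
      label = rep(c("same", "diff"), c(n_same, n_diff)),
      context = context,
      stringsAsFactors = FALSE)
    class(out) <- c("score_sample", "data.frame")
    out
  })
}

# draw until all values fall strictly inside (0, 1)
truncated_draw <- function(n, rfun) {
  x <- rfun(n)
  bad <- which(x <= 0 | x >= 1)
  while (length(bad)) {
    x[bad] <- rfun(length(bad))
    bad <- which(x <= 0 | x >= 1)
  }
  x
}
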