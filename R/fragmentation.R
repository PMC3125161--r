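#' Partition per-site SSE labels into backbone fragments
#'
#' Fragments are the units carrying local rigid transformations.  They are
#' consecutive, non-overlapping, cover every site, and never mix
#' secondary-structure labels.  Within each maximal run of identical
#' labels the rule is applied repeatedly: with `k = min(max_look, sites
#' remaining)`, a run tail of `k = max_look` yields a fragment of `take`
#' sites (leaving at least 3 behind); `k < max_look` yields one fragment
#' of `k` sites.  With the defaults (`max_look = 9`, `take = 6`) most
#' fragments have length 6 and all have length 3..9, except that runs
#' shorter than 3 become fragments as-is.
#'
#' @param sse character vector of per-site labels in `{H,E,C}` (a single
#'   string is also accepted).
#' @param max_look look-ahead window (default 9).
#' @param take fragment size emitted when the look-ahead is full
#'   (default 6).
#' @return A data.frame of class `fragment_set` with columns `index`,
#'   `start`, `end` (1-based inclusive site indices), `length`,
#'   `sse_class`.
#' @export
#' @examples
#' decompose_fragments(strrep("H", 18))$length  # 6 6 6
decompose_fragments <- function(sse, max_look = 9L, take = 6L) {
  if (length(sse) == 1L && nchar(sse) > 1L) sse <- strsplit(sse, "")[[1]]
  stopifnot(length(sse) >= 1L, max_look >= take, take >= 3L)
  r <- rle(as.character(sse))
  starts <- integer(0); ends <- integer(0); cls <- character(0)
  pos <- 1L
  for (ri in seq_along(r$lengths)) {
    left <- r$lengths[ri]
    while (left > 0L) {
      k <- min(max_look, left)
      len <- if (k == max_look) take else k
      starts <- c(starts, pos)
      ends <- c(ends, pos + len - 1L)
      cls <- c(cls, r$values[ri])
      pos <- pos + len
      left <- left - len
    }
  }
  out <- data.frame(index = seq_along(starts), start = starts, end = ends,
                    length = ends - starts + 1L, sse_class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("fragment_set", "data.frame")
  out
}

#' Fragment neighbourhood: the m sites nearest a fragment
#'
#' The distance from a site to a fragment is the shortest 3D distance
#' between the site and any of the fragment's sites.  The `min(m, n)`
#' sites of smallest fragment distance form the neighbourhood; the
#' fragment's own sites (distance 0) are always included when `m` allows.
#' Ties are broken by smaller site index.
#'
#' @param s a [ca_structure()].
#' @param fragment one row of [decompose_fragments()] output (or any list
#'   with `start` and `end`).
#' @param m requested neighbourhood size (sites); the value the original
#'   method tuned on its training set is not public, default 40.
#' @return Sorted integer vector of member site indices (1-based).
#' @export
fragment_neighbourhood <- function(s, fragment, m = 40L) {
  stopifnot(inherits(s, "ca_structure"), m >= 1L)
  idx <- fragment$start:fragment$end
  fx <- s$xyz[idx, , drop = FALSE]
  n <- s$n
  # distance of every site to its nearest fragment site
  d2 <- rep(Inf, n)
  for (k in seq_len(nrow(fx))) {
    dk <- rowSums(sweep(s$xyz, 2L, fx[k, ])^2)
    d2 <- pmin(d2, dk)
  }
  ord <- order(d2, seq_len(n))
  sort(ord[seq_len(min(m, n))])
}

#' All fragments and neighbourhoods of a structure
#'
#' @param s a [ca_structure()] with SSE labels assigned.
#' @param m neighbourhood size, see [fragment_neighbourhood()].
#' @return List with `fragments` (a `fragment_set`), `neighbourhoods`
#'   (list of site-index vectors), and `frag_of` (integer vector mapping
#'   each site to its fragment index).
#' @export
structure_fragments <- function(s, m = 40L) {
  stopifnot(inherits(s, "ca_structure"))
  if (anyNA(s$sse)) stop("SSE labels missing: run assign_sse() first")
  fr <- decompose_fragments(s$sse)
  nb <- lapply(seq_len(nrow(fr)),
               function(i) fragment_neighbourhood(s, fr[i, ], m = m))
  frag_of <- integer(s$n)
  for (i in seq_len(nrow(fr))) frag_of[fr$start[i]:fr$end[i]] <- i
  list(fragments = fr, neighbourhoods = nb, frag_of = frag_of)
}
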