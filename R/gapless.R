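#' Offsets of sliding gapless windows
#'
#' The shorter domain is slid over the longer one starting at the
#' N-terminus with leaps of `leap` residues; an extra window aligning
#' the C-termini is appended when not already present.
#'
#' @param l_short,l_long domain lengths, `l_short <= l_long`.
#' @param leap sliding step in residues (default 20).
#' @return Strictly increasing, unique integer offsets (0-based) of the
#'   window start in the longer domain.
#' @export
#' @examples
#' gapless_offsets(100, 200)  # 0 20 40 60 80 100
gapless_offsets <- function(l_short, l_long, leap = 20L) {
  stopifnot(leap >= 1L)
  if (l_short > l_long)
    stop("l_short must not exceed l_long; order the arguments")
  dmax <- l_long - l_short
  off <- seq(0L, dmax, by = as.integer(leap))
  if (off[length(off)] != dmax) off <- c(off, dmax)
  off
}

#' PD-scores of all gapless windows between two domains
#'
#' For each window the identity correspondence between the shorter
#' domain and an equal-length window of the longer domain is built and
#' evaluated with [evaluate_alignment()].  SSE labels of the window are
#' taken from the full chain; fragment decomposition is re-run on the
#' window (the windows are the objects being scored).
#'
#' @param a,b [ca_structure()]s with SSE labels; order-free (the shorter
#'   is slid over the longer).
#' @param leap sliding step (residues).
#' @param cfg a [pd_config()].
#' @return data.frame with columns `offset`, `length`, `pd_score`, one
#'   row per window.
#' @export
score_gapless <- function(a, b, leap = 20L, cfg = pd_config()) {
  stopifnot(inherits(a, "ca_structure"), inherits(b, "ca_structure"))
  if (a$n > b$n) { tmp <- a; a <- b; b <- tmp }
  offs <- gapless_offsets(a$n, b$n, leap = leap)
  ls <- a$n
  pairs <- cbind(seq_len(ls), seq_len(ls))
  scores <- vapply(offs, function(o) {
    w <- subset_structure(b, (o + 1L):(o + ls),
                          id = paste0(b$id, "_w", o))
    evaluate_alignment(a, w, pairs, cfg = cfg)$pd_score
  }, numeric(1))
  data.frame(offset = offs, length = ls, pd_score = scores)
}
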