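# Independent oracles and fixture builders shared across the test files.

# ---- brute-force block-alignment enumerator -------------------------------
# Recursively enumerates block placements (diagonal runs of length >=
# min_block; adjacent continuations are reachable as longer runs) and
# returns the maximum of the DP objective
#   F = sum S - penalty * ((L1 - Na) + (L2 - Na)).
# Exhaustive and structurally unrelated to the production per-cell DP.
bf_block_align <- function(S, penalty, min_block = 6L) {
  n1 <- nrow(S); n2 <- ncol(S)
  memo <- new.env(hash = TRUE)
  rec <- function(i0, j0) {
    key <- paste0(i0, ",", j0)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    best <- 0
    if (i0 <= n1 && j0 <= n2) {
      for (i in i0:n1) for (j in j0:n2) {
        maxk <- min(n1 - i + 1L, n2 - j + 1L)
        if (maxk < min_block) next
        g <- 0
        for (k in seq_len(maxk)) {
          g <- g + S[i + k - 1L, j + k - 1L] + 2 * penalty
          if (k >= min_block)
            best <- max(best, g + rec(i + k, j + k))
        }
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L) - penalty * (n1 + n2)
}

# Eq-style objective of an explicit pair list (used for the identity check)
alignment_objective <- function(S, pairs, penalty) {
  na <- nrow(pairs)
  sum(S[pairs]) - penalty * ((nrow(S) - na) + (ncol(S) - na))
}

# ---- brute-force fragment neighbourhood -----------------------------------
bf_neighbourhood <- function(xyz, frag_idx, m) {
  n <- nrow(xyz)
  d <- vapply(seq_len(n), function(i) {
    min(sqrt(colSums((t(xyz[frag_idx, , drop = FALSE]) - xyz[i, ])^2)))
  }, numeric(1))
  sort(order(d, seq_len(n))[seq_len(min(m, n))])
}

# ---- random SSE label strings ---------------------------------------------
random_labels <- function(n_runs = 6L) {
  paste(unlist(lapply(seq_len(n_runs), function(i) {
    strrep(sample(c("H", "E", "C"), 1L), sample(1:14, 1L))
  })), collapse = "")
}

# ---- vectorised random-rotation RMSD (Monte-Carlo Kabsch lower bound) -----
# Applies nrot random rigid transforms to P and returns the RMSD to Q of
# each; translations are sampled around the centroid-matching offset so
# the competitors are not trivially bad.
mc_random_rmsd <- function(P, Q, nrot) {
  q <- matrix(rnorm(nrot * 4L), nrot, 4L)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  rot_apply <- function(v) {
    # v' = v + 2 w (u x v) + 2 u x (u x v), u = (x,y,z)
    cx <- y * v[3] - z * v[2]; cy <- z * v[1] - x * v[3]
    cz <- x * v[2] - y * v[1]
    dx <- y * cz - z * cy; dy <- z * cx - x * cz; dz <- x * cy - y * cx
    cbind(v[1] + 2 * (w * cx + dx),
          v[2] + 2 * (w * cy + dy),
          v[3] + 2 * (w * cz + dz))
  }
  n <- nrow(P)
  cp <- colMeans(P); cq <- colMeans(Q)
  tnoise <- matrix(rnorm(nrot * 3L), nrot, 3L)
  rcp <- rot_apply(cp)
  trans <- -rcp + matrix(cq, nrot, 3L, byrow = TRUE) + tnoise
  acc <- 0
  for (i in seq_len(n)) {
    rp <- rot_apply(P[i, ]) + trans
    acc <- acc + (rp[, 1] - Q[i, 1])^2 + (rp[, 2] - Q[i, 2])^2 +
      (rp[, 3] - Q[i, 3])^2
  }
  sqrt(acc / n)
}

# ---- best single rigid superposition coverage -----------------------------
# Iteratively refined global Kabsch fits (all pairs, and each chain half
# as starts); returns the best fraction of identity pairs within `cut` A.
rigid_coverage <- function(xyz_a, xyz_b, cut = 5) {
  n <- nrow(xyz_a)
  starts <- list(seq_len(n), seq_len(n %/% 2), (n %/% 2 + 1L):n)
  best <- 0
  for (s0 in starts) {
    sel <- s0
    for (it in 1:20) {
      tr <- kabsch(xyz_a[sel, , drop = FALSE], xyz_b[sel, , drop = FALSE])
      if (!is_defined(tr)) break
      d <- sqrt(rowSums((transform_coords(tr, xyz_a) - xyz_b)^2))
      nsel <- which(d <= cut)
      if (length(nsel) < 3L || identical(nsel, sel)) { sel <- nsel; break }
      sel <- nsel
    }
    best <- max(best, length(sel) / n)
  }
  best
}

# ---- synthetic toy domains ------------------------------------------------
toy_four_helix <- function(seed, helix_len = 14L, loop_len = 3L) {
  assign_sse(make_domain(list(
    list(kind = "helix", length = helix_len),
    list(kind = "loop", length = loop_len),
    list(kind = "helix", length = helix_len),
    list(kind = "loop", length = loop_len),
    list(kind = "helix", length = helix_len),
    list(kind = "loop", length = loop_len),
    list(kind = "helix", length = helix_len)), seed = seed,
    id = paste0("toy", seed)))
}

# mixed helix/strand/loop domain of approximately n sites
toy_domain_of_length <- function(n, seed) {
  segs <- list()
  left <- n
  kinds <- c("helix", "loop", "strand", "loop")
  k <- 1L
  while (left > 0L) {
    kind <- kinds[(k - 1L) %% length(kinds) + 1L]
    len <- if (kind == "loop") min(3L, left) else min(12L, left)
    segs[[k]] <- list(kind = kind, length = len)
    left <- left - len
    k <- k + 1L
  }
  assign_sse(make_domain(segs, seed = seed, id = paste0("dom", n, "_", seed)))
}

# minimal hand-built PDB text (fixed-width ATOM records)
pdb_atom_line <- function(serial, resseq, x, y, z, chain = "A",
                          altloc = " ", icode = " ", name = " CA ") {
  sprintf("ATOM  %5d %s%s%s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, name, altloc, "ALA", chain, resseq, icode, x, y, z)
}
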