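#' C-alpha structure container
#'
#' A protein chain reduced to its ordered C-alpha trace.  Sites follow
#' chain order; each carries an author residue identifier (number plus
#' optional insertion code) and a secondary-structure label in
#' `{H, E, C}` (`NA` until assigned, see [assign_sse()]).
#'
#' @param xyz n x 3 numeric matrix of C-alpha coordinates in Angstrom.
#' @param id structure identifier (used in reports and tie-breaking).
#' @param residue_ids character vector of author residue ids; defaults to
#'   `1..n`.
#' @param sse per-site labels in `{H,E,C}` or `NA`.
#' @return An object of class `ca_structure` with fields `id`, `xyz`,
#'   `residue_ids`, `sse` and length `n`.
#' @export
ca_structure <- function(xyz, id = "structure", residue_ids = NULL, sse = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  stopifnot(ncol(xyz) == 3L, nrow(xyz) >= 1L, all(is.finite(xyz)))
  n <- nrow(xyz)
  if (is.null(residue_ids)) residue_ids <- as.character(seq_len(n))
  if (is.null(sse)) sse <- rep(NA_character_, n)
  stopifnot(length(residue_ids) == n, length(sse) == n)
  ok <- is.na(sse) | sse %in% c("H", "E", "C")
  if (!all(ok)) stop("sse labels must be in {H, E, C} or NA")
  structure(list(id = as.character(id), xyz = xyz,
                 residue_ids = as.character(residue_ids),
                 sse = as.character(sse), n = n),
            class = "ca_structure")
}

#' @param x a `ca_structure`.
#' @param ... ignored.
#' @rdname ca_structure
#' @export
print.ca_structure <- function(x, ...) {
  lab <- if (all(is.na(x$sse))) "unassigned" else
    paste(table(factor(x$sse, levels = c("H", "E", "C"))), collapse = "/")
  cat(sprintf("<ca_structure '%s': %d sites, SSE (H/E/C): %s>\n",
              x$id, x$n, lab))
  invisible(x)
}

#' @rdname ca_structure
#' @export
length.ca_structure <- function(x) x$n

# take a contiguous subsequence of sites, keeping labels and residue ids
subset_structure <- function(s, idx, id = s$id) {
  ca_structure(s$xyz[idx, , drop = FALSE], id = id,
               residue_ids = s$residue_ids[idx], sse = s$sse[idx])
}

#' Read a C-alpha backbone from a PDB file
#'
#' Parses fixed-width `ATOM` records, keeping one C-alpha per residue.
#' Alternate locations: the first-listed altloc is kept.  Only the first
#' `MODEL` is read unless `model` is given.  `HELIX`/`SHEET` records are
#' retained (as an attribute) for [assign_sse()] `mode = "records"`.
#'
#' No full-featured PDB reader is available in the supported dependency
#' set, so the fixed-column subset needed here is parsed directly.
#'
#' @param path path to a PDB-format file.
#' @param chain chain identifier; default: the first chain encountered.
#' @param model 1-based model index (default: first model).
#' @return A [ca_structure()] (with `sse` unassigned).  Attribute
#'   `helix_sheet` holds parsed HELIX/SHEET ranges.
#' @export
read_pdb_ca <- function(path, chain = NULL, model = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)

  # model selection
  midx <- which(rec == "MODEL ")
  if (length(midx)) {
    want <- if (is.null(model)) 1L else as.integer(model)
    if (want > length(midx)) stop("model ", want, " not present (",
                                  length(midx), " models)")
    from <- midx[want]
    endm <- which(rec == "ENDMDL")
    to <- endm[endm > from][1]
    if (is.na(to)) to <- length(lines)
    keep <- seq(from, to)
  } else {
    if (!is.null(model) && model != 1L) stop("file has a single model")
    keep <- seq_along(lines)
  }

  atom <- lines[keep][rec[keep] == "ATOM  "]
  aname <- substr(atom, 13L, 16L)
  ca <- atom[trimws(aname) == "CA"]
  if (!length(ca)) stop("no C-alpha atoms found in ", path)

  ch <- substr(ca, 22L, 22L)
  if (is.null(chain)) {
    chain <- ch[1]
  } else if (!chain %in% ch) {
    stop("chain '", chain, "' not found; available: ",
         paste(sort(unique(ch)), collapse = ", "))
  }
  ca <- ca[ch == chain]
  if (!length(ca)) stop("no C-alpha atoms in chain ", chain)

  resid <- paste0(trimws(substr(ca, 23L, 26L)), trimws(substr(ca, 27L, 27L)))
  altloc <- substr(ca, 17L, 17L)
  # one CA per residue: keep the first-listed altloc/duplicate
  first <- !duplicated(resid)
  dropped <- sum(!first & altloc %in% c(" ", "A"))  # informational only
  ca <- ca[first]
  resid <- resid[first]

  xyz <- cbind(as.numeric(substr(ca, 31L, 38L)),
               as.numeric(substr(ca, 39L, 46L)),
               as.numeric(substr(ca, 47L, 54L)))
  if (any(!is.finite(xyz))) stop("unparseable coordinates in ", path)

  # HELIX/SHEET ranges for the selected chain (records mode of assign_sse)
  hs <- parse_helix_sheet(lines, chain)

  s <- ca_structure(xyz, id = paste0(basename(path), "_", chain),
                    residue_ids = resid)
  attr(s, "helix_sheet") <- hs
  s
}

parse_helix_sheet <- function(lines, chain) {
  rec <- substr(lines, 1L, 6L)
  hx <- lines[rec == "HELIX "]
  sh <- lines[rec == "SHEET "]
  out <- list()
  for (l in hx) {
    if (substr(l, 20L, 20L) == chain) {
      out[[length(out) + 1L]] <- list(
        kind = "H",
        from = paste0(trimws(substr(l, 22L, 25L)), trimws(substr(l, 26L, 26L))),
        to   = paste0(trimws(substr(l, 34L, 37L)), trimws(substr(l, 38L, 38L))))
    }
  }
  for (l in sh) {
    if (substr(l, 22L, 22L) == chain) {
      out[[length(out) + 1L]] <- list(
        kind = "E",
        from = paste0(trimws(substr(l, 23L, 26L)), trimws(substr(l, 27L, 27L))),
        to   = paste0(trimws(substr(l, 34L, 37L)), trimws(substr(l, 38L, 38L))))
    }
  }
  out
}

#' Write a C-alpha-only PDB file
#'
#' @param s a [ca_structure()].
#' @param path output file path.
#' @param chain single-character chain id for the ATOM records.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(s, path, chain = "A") {
  stopifnot(inherits(s, "ca_structure"), nchar(chain) == 1L)
  num <- suppressWarnings(as.integer(gsub("[^0-9-]", "", s$residue_ids)))
  ico <- gsub("[0-9-]", "", s$residue_ids)
  ico[ico == ""] <- " "
  num[is.na(num)] <- seq_len(s$n)[is.na(num)]
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(s$n), chain, num, substr(ico, 1L, 1L),
    s$xyz[, 1], s$xyz[, 2], s$xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- secondary structure assignment --------------------------------------

# P-SEA style acceptance bands for the CA-only geometric assignment:
# d2 = d(i-2, i+2) windows centred on each interior site.
.sse_bands <- list(
  H = list(d2 = c(5.0, 6.0), d3 = c(4.8, 5.8), d4 = c(5.8, 7.0)),
  E = list(d2 = c(6.1, 7.3), d3 = c(8.5, 10.8), d4 = c(11.3, 13.8))
)

#' Assign secondary-structure labels to a C-alpha structure
#'
#' Three modes:
#' \describe{
#'   \item{`geometric`}{(default) a C-alpha-only geometric rule in the
#'     P-SEA style.  For each window starting at site i the distances
#'     d(i,i+2), d(i,i+3), d(i,i+4) are tested against helix/strand
#'     acceptance bands and the window centre (site i+2) is labelled.
#'     Helix runs shorter than 4 and strand runs shorter than 3 are
#'     demoted to coil.  Distance-based, hence exactly invariant under
#'     rigid motion.}
#'   \item{`records`}{use the HELIX/SHEET ranges parsed by
#'     [read_pdb_ca()].}
#'   \item{`provided`}{use a caller-supplied per-site label string or
#'     character vector.}
#' }
#'
#' @param s a [ca_structure()].
#' @param mode one of `"geometric"`, `"records"`, `"provided"`.
#' @param labels for `mode = "provided"`: character vector of length n, or
#'   a single string of n characters, over the alphabet `{H,E,C}`.
#' @return `s` with the `sse` field filled (every site in `{H,E,C}`).
#' @export
assign_sse <- function(s, mode = c("geometric", "records", "provided"),
                       labels = NULL) {
  stopifnot(inherits(s, "ca_structure"))
  mode <- match.arg(mode)
  n <- s$n
  if (mode == "provided") {
    if (is.null(labels)) stop("mode='provided' requires labels")
    if (length(labels) == 1L && nchar(labels) > 1L)
      labels <- strsplit(labels, "")[[1]]
    if (length(labels) != n)
      stop("label string has length ", length(labels), ", expected ", n)
    if (!all(labels %in% c("H", "E", "C")))
      stop("labels must be over {H, E, C}")
    s$sse <- as.character(labels)
    return(s)
  }
  if (mode == "records") {
    hs <- attr(s, "helix_sheet")
    lab <- rep("C", n)
    for (r in hs) {
      i1 <- match(r$from, s$residue_ids)
      i2 <- match(r$to, s$residue_ids)
      if (!is.na(i1) && !is.na(i2) && i1 <= i2) lab[i1:i2] <- r$kind
    }
    s$sse <- lab
    return(s)
  }
  s$sse <- sse_geometric(s$xyz)
  s
}

# CA-only geometric labels: windows label their centre site; short runs
# are demoted to coil.  Chains shorter than 5 get all-coil.
sse_geometric <- function(xyz, min_helix = 4L, min_strand = 3L) {
  n <- nrow(xyz)
  lab <- rep("C", n)
  if (n >= 5L) {
    d <- function(k) sqrt(rowSums((xyz[seq_len(n - k), , drop = FALSE] -
                                     xyz[(1L + k):n, , drop = FALSE])^2))
    d2 <- d(2L); d3 <- d(3L); d4 <- d(4L)
    for (i in seq_len(n - 4L)) {
      for (kind in c("H", "E")) {
        b <- .sse_bands[[kind]]
        if (d2[i] >= b$d2[1] && d2[i] <= b$d2[2] &&
            d3[i] >= b$d3[1] && d3[i] <= b$d3[2] &&
            d4[i] >= b$d4[1] && d4[i] <= b$d4[2]) {
          lab[i + 2L] <- kind
          break
        }
      }
    }
    # demote runs that are too short to be real SSEs
    r <- rle(lab)
    short <- (r$values == "H" & r$lengths < min_helix) |
      (r$values == "E" & r$lengths < min_strand)
    r$values[short] <- "C"
    lab <- inverse.rle(r)
  }
  lab
}
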