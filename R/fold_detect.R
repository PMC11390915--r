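# Histone-fold detection from CA geometry.
#
# Secondary structure is assigned from CA-only criteria (P-SEA style):
# predicted models always carry CA atoms, so no hydrogen-bond based method
# is needed. The histone fold is then located as the best-scoring
# alpha1-L1-alpha2-L2-alpha3 triple of helix runs.

SSE_DIST_RANGE <- c(4.6, 6.4)    # CA(i)..CA(i+3) distance band, Angstrom
SSE_TORSION_RANGE <- c(35, 75)   # virtual CA torsion band, degrees
SSE_MIN_RUN <- 4L                # H-runs shorter than this smooth to C
SSE_TEMPLATE_RMSD <- 0.65        # ideal-helix window fit rescue, Angstrom

# 4-residue ideal alpha-helix template (rise 1.5 A, 100 deg twist,
# radius 2.3 A), centered; used for the template-fit window rescue
sse_helix_template <- local({
  ph <- -(0:3) * 100 * pi / 180
  m <- cbind(2.3 * cos(ph), 2.3 * sin(ph), (0:3) * 1.5)
  sweep(m, 2, colMeans(m))
})

# virtual dihedral over four points, degrees in (-180, 180]
ca_torsion <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Assign secondary structure from CA geometry
#'
#' A four-residue window i..i+3 is helical when the CA(i) to CA(i+3)
#' distance lies in `[4.6, 6.4]` Angstrom and the virtual torsion over
#' CA(i..i+3) lies in `[35, 75]` degrees; all four residues of a helical
#' window are marked H (so an ideal n-residue helix yields an H-run of
#' exactly n, and terminal residues inherit the call of the last complete
#' window). Everything else is coil (C). With `smooth = TRUE` (default)
#' H-runs shorter than 4 residues are reverted to C; a 4-residue truncated
#' alpha3 helix survives smoothing.
#'
#' @param model an `hf_structure`
#' @param chain chain id
#' @param smooth logical; apply the minimum-run filter
#' @return a single string over `{H, C}`, one character per residue
#' @export
assign_secondary_structure <- function(model, chain, smooth = TRUE) {
  ca <- hf_ca(model, chain)
  n <- nrow(ca)
  if (n < 5L) stop("chain ", chain, " has fewer than 5 CA atoms")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  st <- rep("C", n)
  for (i in seq_len(n - 3L)) {
    d <- sqrt(sum((xyz[i + 3L, ] - xyz[i, ])^2))
    if (d < SSE_DIST_RANGE[1] || d > SSE_DIST_RANGE[2]) next
    tor <- ca_torsion(xyz[i, ], xyz[i + 1L, ], xyz[i + 2L, ], xyz[i + 3L, ])
    if (tor >= SSE_TORSION_RANGE[1] && tor <= SSE_TORSION_RANGE[2])
      st[i:(i + 3L)] <- "H"
  }
  if (smooth) {
    r <- rle(st)
    r$values[r$values == "H" & r$lengths < SSE_MIN_RUN] <- "C"
    st <- inverse.rle(r)
  }
  paste(st, collapse = "")
}

# (start, end, length) of H-runs in an SSE string, positions 1..n
sse_runs <- function(sse) {
  r <- rle(strsplit(sse, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == "H"
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# relaxed window test used for noise-tolerant run refinement: coordinate
# noise easily pushes a single strict window out of band, but a window
# inside a true helix virtually never leaves these wide bands
relaxed_window <- function(xyz, p) {
  n <- nrow(xyz)
  if (p < 1L || p + 3L > n) return(FALSE)
  d <- sqrt(sum((xyz[p + 3L, ] - xyz[p, ])^2))
  if (d < 4.0 || d > 7.0) return(FALSE)
  tor <- ca_torsion(xyz[p, ], xyz[p + 1L, ], xyz[p + 2L, ], xyz[p + 3L, ])
  tor >= 20 && tor <= 100
}

# noise-tolerant H-runs: strict assignment, then (1) closure of
# single-residue gaps whose bridging windows still fit the ideal-helix
# template (a true in-helix split takes several correlated window
# failures; a real linker residue drags the template fit far off), and
# (2) recovery of frayed run ends with the relaxed window test (at most 2
# residues per side, never crossing another run) - run ends hang on
# single strict windows, which coordinate noise flips easily
robust_runs <- function(model, chain) {
  sse <- assign_secondary_structure(model, chain, smooth = TRUE)
  st <- strsplit(sse, "")[[1]]
  n <- length(st)
  xyz <- as.matrix(hf_ca(model, chain)[, c("x", "y", "z")])
  r0 <- sse_runs(paste(st, collapse = ""))
  for (g in seq_len(n)) {
    if (st[g] != "C") next
    if (g <= 4L || g + 4L > n) next
    if (!(all(st[(g - 4L):(g - 1L)] == "H") && all(st[(g + 1L):(g + 4L)] == "H")))
      next
    # never build a run longer than the alpha2 band: a closure that long
    # would be bridging a real linker, not a noise split
    left <- r0[r0$end == g - 1L, ]; right <- r0[r0$start == g + 1L, ]
    if (nrow(left) && nrow(right) && left$length + right$length + 1L > 34L) next
    for (p in (g - 3L):g) {
      if (p < 1L || p + 3L > n) next
      d <- sqrt(sum((xyz[p + 3L, ] - xyz[p, ])^2))
      if (d > 7.5) next
      if (kabsch(xyz[p:(p + 3L), ], sse_helix_template)$rmsd <= SSE_TEMPLATE_RMSD) {
        st[g] <- "H"
        break
      }
    }
  }
  runs <- sse_runs(paste(st, collapse = ""))
  if (!nrow(runs)) return(runs)
  for (k in seq_len(nrow(runs))) {
    lower <- if (k == 1L) 1L else runs$end[k - 1L] + 2L
    upper <- if (k == nrow(runs)) n else runs$start[k + 1L] - 2L
    for (step in 1:2) {
      s <- runs$start[k] - 1L
      if (s >= lower && relaxed_window(xyz, s)) runs$start[k] <- s
    }
    for (step in 1:2) {
      e <- runs$end[k] + 1L
      if (e <= upper && relaxed_window(xyz, e - 3L)) runs$end[k] <- e
    }
  }
  runs$length <- runs$end - runs$start + 1L
  runs
}

# acceptance bands for the three helices and linkers
FOLD_BANDS <- list(a1 = c(6L, 16L), a2 = c(18L, 34L), a3 = c(2L, 14L),
                   linker = c(1L, 8L))

#' Locate the histone fold in a chain
#'
#' Searches the CA-geometry secondary-structure string for an
#' alpha1-L1-alpha2-L2-alpha3 triple of helix runs with alpha1 in 6-16,
#' alpha2 in 18-34, alpha3 in 2-14 residues and linkers of 1-8 residues.
#' Truncated alpha3 helices (3-4 residues, below common SSE minimums) are
#' rescued by a dedicated relaxed single-window test within 8 residues
#' after alpha2 when no regular H-run qualifies there. Among qualifying
#' triples the one with the longest alpha2 wins, ties going to the most
#' N-terminal.
#'
#' @param model an `hf_structure`
#' @param chain chain id
#' @return an object of class `hf_fold` (fields `chain`, `alpha1`, `alpha2`,
#'   `alpha3` each `(start, end, length)` in 1-based chain positions,
#'   `l1_length`, `l2_length`, `fold_span`, `fold_family`, `n_res`), or
#'   `NULL` when no fold is present (absence is a valid result).
#' @export
detect_histone_fold <- function(model, chain) {
  ca <- hf_ca(model, chain)
  if (nrow(ca) < 30L) return(NULL)
  runs <- robust_runs(model, chain)
  raw_runs <- sse_runs(assign_secondary_structure(model, chain, smooth = FALSE))
  ann <- fold_from_runs(model, chain, runs, raw_runs)
  if (!is.null(ann)) return(ann)
  # recovery: coordinate noise can fuse two helices across a linker into
  # one run; split overlong runs at their worst-fitting window and retry
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  for (k in which(runs$length >= 20L)) {
    s <- runs$start[k]; e <- runs$end[k]
    ps <- seq(s + 4L, e - 7L)
    if (!length(ps)) next
    rms <- vapply(ps, function(p)
      kabsch(xyz[p:(p + 3L), ], sse_helix_template)$rmsd, numeric(1))
    w <- ps[which.max(rms)]
    if (max(rms) <= SSE_TEMPLATE_RMSD) next
    alt <- rbind(runs[-k, ],
                 data.frame(start = s, end = w, length = w - s + 1L),
                 data.frame(start = w + 3L, end = e, length = e - w - 2L))
    alt <- alt[alt$length >= 2L, ]
    alt <- alt[order(alt$start), ]
    ann <- fold_from_runs(model, chain, alt, raw_runs)
    if (!is.null(ann)) return(ann)
  }
  NULL
}

fold_from_runs <- function(model, chain, runs, raw_runs) {
  if (nrow(runs) < 2L) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(runs))) {
    a1 <- runs[i, ]
    if (a1$length < FOLD_BANDS$a1[1] || a1$length > FOLD_BANDS$a1[2]) next
    for (j in seq_len(nrow(runs))) {
      a2 <- runs[j, ]
      if (a2$start <= a1$end) next
      l1 <- a2$start - a1$end - 1L
      if (l1 < FOLD_BANDS$linker[1] || l1 > FOLD_BANDS$linker[2]) next
      if (a2$length < FOLD_BANDS$a2[1] || a2$length > FOLD_BANDS$a2[2]) next
      # alpha3: smoothed run, a short raw run, or a relaxed-window
      # truncated helix right after alpha2
      cand3 <- rbind(runs, raw_runs[raw_runs$length >= 2L & raw_runs$length <= 3L, ])
      if (!any(cand3$start > a2$end & cand3$start - a2$end - 1L <= FOLD_BANDS$linker[2])) {
        tr <- truncated_alpha3(model, chain, a2$end)
        if (!is.null(tr)) cand3 <- rbind(cand3, tr)
      }
      for (k in seq_len(nrow(cand3))) {
        a3 <- cand3[k, ]
        if (a3$start <= a2$end) next
        l2 <- a3$start - a2$end - 1L
        if (l2 < FOLD_BANDS$linker[1] || l2 > FOLD_BANDS$linker[2]) next
        if (a3$length < FOLD_BANDS$a3[1] || a3$length > FOLD_BANDS$a3[2]) next
        cand <- list(a1 = a1, a2 = a2, a3 = a3, l1 = l1, l2 = l2)
        if (is.null(best) ||
            a2$length > best$a2$length ||
            (a2$length == best$a2$length && a1$start < best$a1$start)) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  seg <- function(r) c(start = r$start, end = r$end, length = r$length)
  ann <- structure(list(
    chain = chain,
    alpha1 = seg(best$a1), alpha2 = seg(best$a2), alpha3 = seg(best$a3),
    l1_length = best$l1, l2_length = best$l2,
    fold_span = c(start = best$a1$start, end = best$a3$end),
    n_res = nrow(hf_ca(model, chain)),
    fold_family = NA_character_
  ), class = "hf_fold")
  ann$fold_family <- classify_fold_family(ann)
  ann
}

#' @export
print.hf_fold <- function(x, ...) {
  cat(sprintf("<hf_fold> chain %s: a1 %d-%d (%d) | L1 %d | a2 %d-%d (%d) | L2 %d | a3 %d-%d (%d)  family=%s\n",
              x$chain, x$alpha1["start"], x$alpha1["end"], x$alpha1["length"],
              x$l1_length, x$alpha2["start"], x$alpha2["end"], x$alpha2["length"],
              x$l2_length, x$alpha3["start"], x$alpha3["end"], x$alpha3["length"],
              x$fold_family))
  invisible(x)
}

#' Call the fold family from helix lengths
#'
#' The alpha3-truncated family has a 3-4 residue alpha3 against the 10
#' residue nucleosomal alpha3; the decision bands (alpha3 <= 5 -> alpha3,
#' >= 8 -> nucleosomal, 6-7 -> ambiguous) absorb helix-end fraying. A
#' shortened alpha2 (<= 26 vs >= 27) is recorded as corroborating evidence
#' but is never decisive.
#'
#' @param ann an `hf_fold` annotation
#' @return one of "nucleosomal", "alpha3", "ambiguous"; attribute
#'   `alpha2_short` carries the corroborating alpha2 evidence
#' @export
classify_fold_family <- function(ann) {
  a3 <- as.integer(ann$alpha3["length"])
  fam <- if (a3 <= 5L) "alpha3" else if (a3 >= 8L) "nucleosomal" else "ambiguous"
  attr(fam, "alpha2_short") <- as.integer(ann$alpha2["length"]) <= 26L
  fam
}

# relaxed single-window search for a 4-residue truncated alpha3 helix
# within 8 residues after the alpha2 end (wider distance/torsion bands:
# one jittered window is all the evidence a 3-4 residue helix leaves)
truncated_alpha3 <- function(model, chain, a2_end) {
  ca <- hf_ca(model, chain)
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(ca)
  if (a2_end + 2L > n - 3L) return(NULL)
  for (p in seq(a2_end + 2L, min(a2_end + 9L, n - 3L))) {
    d <- sqrt(sum((xyz[p + 3L, ] - xyz[p, ])^2))
    if (d < 3.9 || d > 7.0) next
    tor <- ca_torsion(xyz[p, ], xyz[p + 1L, ], xyz[p + 2L, ], xyz[p + 3L, ])
    if (tor >= 20 && tor <= 100)
      return(data.frame(start = p, end = p + 3L, length = 4L))
  }
  NULL
}

# residue positions (1-based chain positions) of fold elements
fold_positions <- function(ann, element = c("alpha1", "alpha2", "alpha3",
                                            "l1", "l2", "alpha2_last8",
                                            "fold", "post_fold", "pre_fold")) {
  element <- match.arg(element)
  switch(element,
    alpha1 = seq(ann$alpha1["start"], ann$alpha1["end"]),
    alpha2 = seq(ann$alpha2["start"], ann$alpha2["end"]),
    alpha3 = seq(ann$alpha3["start"], ann$alpha3["end"]),
    l1 = if (ann$l1_length > 0) seq(ann$alpha1["end"] + 1L, ann$alpha2["start"] - 1L) else integer(),
    l2 = if (ann$l2_length > 0) seq(ann$alpha2["end"] + 1L, ann$alpha3["start"] - 1L) else integer(),
    alpha2_last8 = seq(max(ann$alpha2["start"], ann$alpha2["end"] - 7L), ann$alpha2["end"]),
    fold = seq(ann$fold_span["start"], ann$fold_span["end"]),
    post_fold = if (ann$fold_span["end"] < ann$n_res) seq(ann$fold_span["end"] + 1L, ann$n_res) else integer(),
    pre_fold = if (ann$fold_span["start"] > 1L) seq(1L, ann$fold_span["start"] - 1L) else integer()
  )
}
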