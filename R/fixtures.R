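# Synthetic fixture generator.
#
# Builds idealized histone-fold monomers, dimers, and tetramers in every
# supported quaternary topology, together with matching sequences, pLDDT
# tracks and block PAE matrices. Fixtures aim for classifier-unambiguous
# geometry, not physical realism: helices are ideal (1.5 A rise, 100 deg
# twist, 2.3 A radius), linkers are interpolated coil, and assemblies are
# rigid-body placements checked only against a 2.5 A minimum inter-atom
# distance. All randomness is seeded per artifact.

HELIX_RISE <- 1.5
HELIX_TWIST <- 100 * pi / 180
HELIX_RADIUS <- 2.3
CONNECTOR_LEN <- 4L   # coil residues inserted before structured flanks

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

unit <- function(v) v / sqrt(sum(v^2))

# orthonormal frame perpendicular to axis
helix_frame <- function(axis) {
  axis <- unit(axis)
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit(ref - sum(ref * axis) * axis)
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = v)
}

# n CA positions of an ideal right-handed alpha helix along `axis`
# starting at `origin` (axis point of the first residue)
helix_points <- function(n, origin, axis, phase0 = 0) {
  axis <- unit(axis)
  fr <- helix_frame(axis)
  t(vapply(seq_len(n), function(i) {
    ph <- phase0 - (i - 1L) * HELIX_TWIST  # sign gives +50 deg CA torsion
    origin + (i - 1L) * HELIX_RISE * axis +
      HELIX_RADIUS * (cos(ph) * fr$u + sin(ph) * fr$v)
  }, numeric(3)))
}

# n coil points strictly between two anchor points, routed along an arc
# bulging perpendicular to the gap so consecutive residues keep extended
# (~3.6 A) spacing; extended spacing puts every window far outside the
# helix bands, so linkers never read as helix even under coordinate noise
coil_points <- function(n, from, to, bulge = NULL) {
  if (n == 0L) return(matrix(numeric(), 0, 3))
  gap <- to - from
  L <- sqrt(sum(gap^2))
  fr <- helix_frame(gap)
  bdir <- if (is.null(bulge)) fr$u else {
    b <- bulge - sum(bulge * unit(gap)) * unit(gap)
    if (sum(b^2) < 1e-8) fr$u else unit(b)
  }
  target <- 3.3 * (n + 1L)
  h <- sqrt(max(0, (target / 2)^2 - (L / 2)^2))
  mid <- (from + to) / 2 + h * bdir
  t(vapply(seq_len(n), function(i) {
    f <- i / (n + 1L)
    p <- if (f <= 0.5) from + (mid - from) * (f / 0.5)
         else mid + (to - mid) * ((f - 0.5) / 0.5)
    p + 0.4 * (-1)^i * fr$v
  }, numeric(3)))
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
}

#' Fold architecture for the fixture generator
#'
#' @param alpha1,alpha2,alpha3 helix lengths (residues)
#' @param l1,l2 linker lengths (residues)
#' @param n_flank,c_flank flank specs: `list(length =, kind =)` with kind
#'   one of "none", "charged_tail" (with `sign` +1/-1), "compact_domain",
#'   "tm_segment", "cc_extension", "ihf_tail"; structured flanks get a
#'   4-residue coil connector in addition to `length`
#' @return list of class `hf_arch`
#' @export
fold_architecture <- function(alpha1 = 11L, alpha2 = 29L, alpha3 = 10L,
                              l1 = 3L, l2 = 3L,
                              n_flank = list(length = 0L, kind = "none"),
                              c_flank = list(length = 0L, kind = "none")) {
  if (any(c(alpha1, alpha2, alpha3, l1, l2) < 1L)) stop("lengths must be >= 1")
  for (f in list(n_flank, c_flank)) {
    if (!f$kind %in% c("none", "charged_tail", "compact_domain", "tm_segment",
                       "cc_extension", "ihf_tail"))
      stop("unknown flank kind: ", f$kind)
    if (f$kind != "none" && f$length < 1L) stop("flank of kind ", f$kind,
                                                " needs a positive length")
  }
  structure(list(alpha1 = as.integer(alpha1), alpha2 = as.integer(alpha2),
                 alpha3 = as.integer(alpha3), l1 = as.integer(l1),
                 l2 = as.integer(l2), n_flank = n_flank, c_flank = c_flank),
            class = "hf_arch")
}

#' Nucleosomal preset: helices 11/29/10, linkers 3/3
#' @param ... overrides passed to [fold_architecture()]
#' @export
arch_nucleosomal <- function(...) fold_architecture(11L, 29L, 10L, 3L, 3L, ...)

#' Alpha3-truncated preset: helices 11/25/4, linkers 3/3
#' @param ... overrides passed to [fold_architecture()]
#' @export
arch_alpha3 <- function(...) fold_architecture(11L, 25L, 4L, 3L, 3L, ...)

flank_total <- function(f) {
  if (f$kind == "none") 0L
  else if (f$kind %in% c("charged_tail", "tm_segment")) as.integer(f$length)
  else as.integer(f$length) + CONNECTOR_LEN
}

#' Total residue count of an architecture
#' @param arch an `hf_arch`
#' @export
arch_length <- function(arch) {
  arch$alpha1 + arch$l1 + arch$alpha2 + arch$l2 + arch$alpha3 +
    flank_total(arch$n_flank) + flank_total(arch$c_flank)
}

# expected fold element positions (1-based) of a generated chain
arch_truth <- function(arch) {
  nf <- flank_total(arch$n_flank)
  a1s <- nf + 1L; a1e <- a1s + arch$alpha1 - 1L
  a2s <- a1e + arch$l1 + 1L; a2e <- a2s + arch$alpha2 - 1L
  a3s <- a2e + arch$l2 + 1L; a3e <- a3s + arch$alpha3 - 1L
  list(alpha1 = c(a1s, a1e), alpha2 = c(a2s, a2e), alpha3 = c(a3s, a3e),
       fold_span = c(a1s, a3e), n_res = arch_length(arch))
}

# CA trace of the fold core in the local frame: alpha2 along +x centered at
# the origin, alpha1 on the -y (DNA-binding) face, alpha3 sticking out at
# the +x end toward +y (the tetramerization side)
fold_core_coords <- function(arch) {
  half2 <- (arch$alpha2 - 1L) * HELIX_RISE / 2
  a2 <- helix_points(arch$alpha2, c(-half2, 0, 0), c(1, 0, 0))
  a1_end_x <- -half2 + 1
  a1_start_x <- a1_end_x + (arch$alpha1 - 1L) * HELIX_RISE
  a1 <- helix_points(arch$alpha1, c(a1_start_x, -9, 0), c(-1, 0, 0))
  l1 <- coil_points(arch$l1, a1[nrow(a1), ], a2[1, ], bulge = c(0, 0, 1))
  a3_origin <- c(half2 + 5.5, 2.5, -1.5)
  a3 <- helix_points(arch$alpha3, a3_origin, c(0, 1, 0))
  l2 <- coil_points(arch$l2, a2[nrow(a2), ], a3[1, ], bulge = c(0, 0, 1))
  rbind(a1, l1, a2, l2, a3)
}

# append flank coordinates; fold_xyz is the core trace in its final frame
flank_coords <- function(f, side, anchor, away) {
  n <- f$length
  if (f$kind == "none") return(matrix(numeric(), 0, 3))
  if (f$kind %in% c("charged_tail", "tm_segment")) {
    # extended chain marching away from the body
    dirv <- unit(away)
    pts <- t(vapply(seq_len(n), function(i)
      anchor + (3.6 * i) * dirv + 0.5 * (-1)^i * helix_frame(dirv)$u,
      numeric(3)))
    if (side == "N") pts <- pts[rev(seq_len(n)), , drop = FALSE]
    return(pts)
  }
  if (f$kind == "compact_domain") {
    # tight solenoid around the away axis: non-helical per-window geometry,
    # small radius of gyration (compact), ~3.8 A consecutive spacing; the
    # anchor-side terminus of the domain is its nearest residue, so the
    # connector never crosses other turns
    dirv <- unit(away)
    fr <- helix_frame(dirv)
    pts <- t(vapply(seq_len(n), function(i) {
      t_i <- if (side == "N") n - i else i - 1L
      ph <- t_i * 45 * pi / 180
      anchor + (7 + 0.55 * t_i) * dirv +
        5 * (cos(ph) * fr$u + sin(ph) * fr$v)
    }, numeric(3)))
    conn_to <- if (side == "N") pts[n, ] else pts[1, ]
    conn <- coil_points(CONNECTOR_LEN, anchor, conn_to)
    if (side == "N") rbind(pts, conn[rev(seq_len(CONNECTOR_LEN)), , drop = FALSE])
    else rbind(conn, pts)
  } else stop("flank kind ", f$kind, " is placed by the assembler, not here")
}

#' Build an idealized histone-fold monomer
#'
#' @param arch an `hf_arch` (see [arch_nucleosomal()], [arch_alpha3()])
#' @param seed integer seed fixing all randomness (jitter)
#' @param jitter_sigma Gaussian coordinate noise, Angstrom
#' @param sequence optional amino-acid string of length `arch_length(arch)`
#'   used for residue names (default poly-Ala-like placeholder from
#'   [synth_sequence_set()] background is NOT applied; plain "ALA" is used)
#' @param chain chain id
#' @param plddt constant pLDDT written to all residues (default 90)
#' @return list: `model` (an `hf_structure`), `truth` (expected fold element
#'   spans from the architecture)
#' @export
build_fold_monomer <- function(arch, seed = 1L, jitter_sigma = 0,
                               sequence = NULL, chain = "A", plddt = 90) {
  xyz <- monomer_coords(arch)
  model <- coords_to_model(list(xyz), chains = chain, sequences = sequence,
                           plddt = plddt)
  check_min_separation(model)  # on ideal coordinates; jitter is noise
  model <- apply_jitter(model, seed, jitter_sigma)
  list(model = model, truth = arch_truth(arch))
}

# full monomer trace in the local frame (fold core + flanks)
monomer_coords <- function(arch) {
  core <- fold_core_coords(arch)
  nfl <- arch$n_flank; cfl <- arch$c_flank
  npts <- matrix(numeric(), 0, 3); cpts <- matrix(numeric(), 0, 3)
  if (nfl$kind %in% c("charged_tail", "tm_segment", "compact_domain"))
    npts <- flank_coords(nfl, "N", core[1, ], away = c(0, -1, 0.15))
  if (cfl$kind %in% c("charged_tail", "tm_segment", "compact_domain"))
    cpts <- flank_coords(cfl, "C", core[nrow(core), ], away = c(0.3, 1, -0.2))
  # cc_extension / ihf_tail in a monomer: straight helix continuing +y
  if (cfl$kind == "cc_extension") {
    start <- core[nrow(core), ] + c(2, 4, 0)
    hx <- helix_points(cfl$length, start, c(0, 1, 0))
    cpts <- rbind(coil_points(CONNECTOR_LEN, core[nrow(core), ], hx[1, ]), hx)
  }
  if (cfl$kind == "ihf_tail") {
    cpts <- ihf_tail_coords(cfl, core[nrow(core), ], sx = 1, z = 4)
  }
  rbind(npts, core, cpts)
}

# coil along a polyline of waypoints, n points at even arclength
coil_via <- function(n, waypoints) {
  seglen <- sqrt(rowSums(diff(waypoints)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  interp <- function(s) {
    k <- max(which(cum <= s + 1e-9)); k <- min(k, nrow(waypoints) - 1L)
    f <- (s - cum[k]) / seglen[k]
    waypoints[k, ] + f * (waypoints[k + 1L, ] - waypoints[k, ])
  }
  t(vapply(seq_len(n), function(i) {
    p <- interp(total * i / (n + 1L))
    p + 0.9 * (-1)^i * c(0, 0, 1)
  }, numeric(3)))
}

# two short antiparallel helices meeting under the dimer center; the two
# chains' tails sit at z = +4 / -4 (sx mirrors chain B in x) and pack
# against the partner's tail in a handshake-like motif. The connector is
# routed around the dimer end, outside the fold core.
ihf_tail_coords <- function(f, anchor, sx, z) {
  if (f$length < 10L) stop("ihf_tail needs at least 10 residues")
  n1 <- (f$length - 2L) %/% 2L; n2 <- f$length - 2L - n1
  h1s <- c(sx * (n1 - 1) * HELIX_RISE / 2, -19.5, z)
  h1 <- helix_points(n1, h1s, c(-sx, 0, 0))
  h2s <- c(-sx * (n2 - 1) * HELIX_RISE / 2, -27.5, z)
  h2 <- helix_points(n2, h2s, c(sx, 0, 0))
  turn <- coil_points(2L, h1[n1, ], h2[1, ], bulge = c(-sx, 0, 0))
  conn <- coil_via(CONNECTOR_LEN, rbind(
    anchor, c(sx * 34, 14, z * 0.8), c(sx * 24, -15, z), h1[1, ]))
  rbind(conn, h1, turn, h2)
}

# assemble an hf_structure from per-chain coordinate matrices
coords_to_model <- function(xyz_list, chains, sequences = NULL, plddt = 90) {
  atoms <- NULL
  for (k in seq_along(xyz_list)) {
    xyz <- xyz_list[[k]]
    n <- nrow(xyz)
    resn <- if (!is.null(sequences)) {
      s <- sequences[[min(k, length(sequences))]]
      if (nchar(s) != n) stop("sequence length ", nchar(s),
                              " does not match chain length ", n)
      unname(AA_ONE_TO_THREE[strsplit(s, "")[[1]]])
    } else rep("ALA", n)
    atoms <- rbind(atoms, data.frame(
      chain = chains[k], resi = seq_len(n), resn = resn, atom = "CA",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], plddt = plddt,
      stringsAsFactors = FALSE))
  }
  hf_structure(atoms)
}

apply_jitter <- function(model, seed, jitter_sigma) {
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  if (jitter_sigma == 0) return(model)
  with_seed(seed, {
    n <- nrow(model$atoms)
    model$atoms$x <- model$atoms$x + rnorm(n, 0, jitter_sigma)
    model$atoms$y <- model$atoms$y + rnorm(n, 0, jitter_sigma)
    model$atoms$z <- model$atoms$z + rnorm(n, 0, jitter_sigma)
  })
  model
}

check_min_separation <- function(model, min_dist = 2.5) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  ch <- model$atoms$chain
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  # near neighbors along a chain (bonded stretch, helix curl after a
  # connector) may be closer than the clash floor
  same_chain <- outer(ch, ch, "==")
  idx <- abs(outer(seq_along(ch), seq_along(ch), "-")) <= 6
  d[same_chain & idx] <- Inf
  if (min(d) < min_dist)
    stop(sprintf("fixture geometry clash: min separation %.2f A < %.2f A",
                 min(d), min_dist))
  invisible(TRUE)
}

#' Assemble an oligomer fixture in a named topology
#'
#' Topologies: `monomer`, `handshake_dimer` (alpha2 axes crossing ~30 deg),
#' `ftf_tetramer` (two dimers closed into a torus through both ends:
#' alpha3 + last 8 of alpha2), `cc_tetramer` (four C-terminal extension
#' helices in a bundle), `ctail_tetramer` (dimers joined through two
#' separate C-flank patches, no bundle), `open_stack_tetramer` (a single
#' FtF-style interface), `separated_chains` (chains >= 20 A apart),
#' `ihf_dimer` (handshake dimer with dimerizing two-helix C-tails).
#'
#' @param arch an `hf_arch`
#' @param topology topology name
#' @param seed integer; fixes jitter
#' @param jitter_sigma Gaussian coordinate noise (Angstrom)
#' @param sequence optional per-chain amino-acid string (recycled)
#' @param plddt constant pLDDT for all residues
#' @return list: `model`, `truth` (fold spans per chain plus the intended
#'   `topology` ground truth)
#' @export
assemble_oligomer <- function(arch, topology = c("monomer", "handshake_dimer",
                                                 "ftf_tetramer", "cc_tetramer",
                                                 "ctail_tetramer",
                                                 "open_stack_tetramer",
                                                 "separated_chains", "ihf_dimer"),
                              seed = 1L, jitter_sigma = 0, sequence = NULL,
                              plddt = 90) {
  topology <- match.arg(topology)
  if (topology %in% c("cc_tetramer", "ctail_tetramer") &&
      arch$c_flank$kind != "cc_extension")
    stop(topology, " requires a cc_extension C-flank in the architecture")
  if (topology == "ihf_dimer" && arch$c_flank$kind != "ihf_tail")
    stop("ihf_dimer requires an ihf_tail C-flank")
  seqs <- if (is.null(sequence)) NULL else as.list(sequence)
  build <- function(xyz_list, chains) {
    m <- coords_to_model(xyz_list, chains, sequences = seqs, plddt = plddt)
    check_min_separation(m)  # on ideal coordinates; jitter is noise
    apply_jitter(m, seed, jitter_sigma)
  }
  truth1 <- arch_truth(arch)
  out <- switch(topology,
    monomer = {
      list(xyz = list(monomer_coords(arch)), chains = "A")
    },
    handshake_dimer = ,
    ihf_dimer = {
      list(xyz = dimer_coords(arch), chains = c("A", "B"))
    },
    separated_chains = {
      base <- monomer_coords(arch)
      ext <- max(dist(base)) + 25
      list(xyz = list(base,
                      sweep(base, 2, c(0, 0, ext), "+"),
                      sweep(base, 2, c(ext, 0, 0), "+"),
                      sweep(base, 2, c(ext, 0, ext), "+")),
           chains = c("A", "B", "C", "D"))
    },
    ftf_tetramer = tetramer_coords(arch, mode = "ftf"),
    open_stack_tetramer = tetramer_coords(arch, mode = "open"),
    cc_tetramer = cc_tetramer_coords(arch, bundle = TRUE),
    ctail_tetramer = cc_tetramer_coords(arch, bundle = FALSE)
  )
  model <- build(out$xyz, out$chains)
  truth <- list(topology = topology, arch = arch,
                chains = stats::setNames(rep(list(truth1), length(out$chains)),
                                         out$chains))
  list(model = model, truth = truth)
}

# handshake dimer: chain A = Rz(15) M shifted +z; chain B = C2 image of A
# about the y axis. The alpha2 axes cross at 30 deg, both alpha1 helices
# form the -y (DNA-binding) face, and both alpha3 + alpha2-C-terminal ends
# protrude toward +y at the two x extremes of the dimer.
dimer_coords <- function(arch, dz = 4) {
  core_arch <- arch
  ihf <- arch$c_flank$kind == "ihf_tail"
  if (ihf) core_arch$c_flank <- list(length = 0L, kind = "none")
  m <- monomer_coords(core_arch)
  a <- sweep(m %*% t(rot_z(15)), 2, c(0, 0, dz), "+")
  c2y <- diag(c(-1, 1, -1))
  b <- a %*% t(c2y)
  if (ihf) {
    a <- rbind(a, ihf_tail_coords(arch$c_flank, a[nrow(a), ], sx = 1, z = 4))
    b <- rbind(b, ihf_tail_coords(arch$c_flank, b[nrow(b), ], sx = -1, z = -4))
  }
  list(a, b)
}

# FtF torus / open stack: dimer 2 is dimer 1 rotated 180 deg about x and
# shifted +y until no atoms clash, which leaves only the protruding end
# elements (alpha3 + last 8 of alpha2) in contact; "open" additionally
# swings dimer 2 about the +x interface so the -x end separates
tetramer_coords <- function(arch, mode = c("ftf", "open")) {
  mode <- match.arg(mode)
  d1 <- dimer_coords(arch)
  all1 <- do.call(rbind, d1)
  m2 <- lapply(d1, function(m) m %*% t(rot_x(180)))
  pivot_x <- max(all1[, 1])
  place <- function(D) {
    d2 <- lapply(m2, function(m) sweep(m, 2, c(0, D, 0), "+"))
    if (mode == "open") {
      pivot <- c(pivot_x, D / 2, 0)
      d2 <- lapply(d2, function(m)
        sweep(sweep(m, 2, pivot) %*% t(rot_z(-25)), 2, pivot, "+"))
    }
    d2
  }
  # the dimers face each other parentheses-style: only the +y-protruding
  # alpha3 tips of d1 meet the -y-pointing alpha3 tips of d2
  tr <- arch_truth(arch)
  a3rows <- seq(tr$alpha3[1], tr$alpha3[2])
  max3 <- max(vapply(d1, function(m) max(m[a3rows, 2]), numeric(1)))
  off <- 2 * max3 + 3.2
  repeat {
    d2 <- place(off)
    if (min(crossdist(all1, do.call(rbind, d2))) >= 2.8) break
    off <- off + 0.5
    if (off > 200) stop("could not place the tetramer without clashes")
  }
  if (mode == "open") {
    # the swing opens both ends a little; pull dimer 2 back in until the
    # retained +x interface is at contact distance again
    repeat {
      d2_try <- place(off - 0.25)
      if (min(crossdist(all1, do.call(rbind, d2_try))) < 2.8) break
      off <- off - 0.25
      d2 <- d2_try
      if (min(crossdist(all1, do.call(rbind, d2))) <= 4.8) break
    }
  }
  list(xyz = c(d1, d2), chains = c("A", "B", "C", "D"))
}

crossdist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

# CC bundle / C-tail tetramer: two fold-core dimers 50 A apart, the four
# C-terminal extension helices either bundled around the midline (bundle)
# or paired off in two separate patches (no bundle)
cc_tetramer_coords <- function(arch, bundle = TRUE) {
  core_arch <- arch
  core_arch$c_flank <- list(length = 0L, kind = "none")
  d1 <- dimer_coords(core_arch)
  len <- arch$c_flank$length
  sep <- max(56, (len - 1L) * HELIX_RISE + 20)
  d2 <- lapply(d1, function(m)
    sweep(m %*% t(rot_x(180)), 2, c(0, sep, 0), "+"))
  len <- arch$c_flank$length
  # corner x signs follow each chain's alpha3 end so connectors do not
  # cross the partner dimer's extensions
  if (bundle) {
    corners <- list(A = c(4.5, 4.5), B = c(-4.5, -4.5),
                    C = c(4.5, -4.5), D = c(-4.5, 4.5))
  } else {
    corners <- list(A = c(14, 4), B = c(-14, -4), C = c(14, -4), D = c(-14, 4))
  }
  span <- (len - 1L) * HELIX_RISE
  y0 <- (sep - span) / 2
  add_ext <- function(m, corner, updir) {
    start <- c(corner[1], if (updir > 0) y0 else sep - y0, corner[2])
    conn_bulge <- c(0, 0, sign(corner[2]))
    axis <- c(0, updir, 0)
    # first helix residue faces the incoming connector so the following
    # turns spiral away from it
    fr <- helix_frame(axis)
    r <- m[nrow(m), ] - start
    r <- r - sum(r * axis) * axis
    ph0 <- atan2(sum(r * fr$v), sum(r * fr$u))
    hx <- helix_points(len, start, axis, phase0 = ph0)
    rbind(m, coil_points(CONNECTOR_LEN, m[nrow(m), ], hx[1, ],
                         bulge = conn_bulge), hx)
  }
  list(xyz = list(add_ext(d1[[1]], corners$A, +1),
                  add_ext(d1[[2]], corners$B, +1),
                  add_ext(d2[[1]], corners$C, -1),
                  add_ext(d2[[2]], corners$D, -1)),
       chains = c("A", "B", "C", "D"))
}

#' Synthesize pLDDT tracks and a block PAE matrix for a model
#'
#' Residues inside each chain's fold span (from `truth`) get `core_plddt`,
#' flanking residues get `tail_plddt`. The PAE matrix is `intra_pae` on the
#' intra-chain blocks and `inter_pae` on every inter-chain block.
#'
#' @param model an `hf_structure`
#' @param truth truth record from [assemble_oligomer()] (or NULL: all
#'   residues are core)
#' @param core_plddt,tail_plddt pLDDT levels (0-100)
#' @param intra_pae,inter_pae PAE levels (Angstrom, >= 0)
#' @return list: `model` (pLDDT written in), `pae` (an `hf_pae`)
#' @export
synth_confidence <- function(model, truth = NULL, core_plddt = 90,
                             tail_plddt = 30, intra_pae = 3, inter_pae = 5) {
  stopifnot(core_plddt >= 0, core_plddt <= 100, tail_plddt >= 0,
            tail_plddt <= 100, intra_pae >= 0, inter_pae >= 0)
  chains <- hf_chains(model)
  lens <- vapply(chains, function(ch) nrow(hf_ca(model, ch)), integer(1))
  for (ch in chains) {
    sel <- model$atoms$chain == ch
    p <- rep(core_plddt, sum(sel))
    if (!is.null(truth)) {
      span <- truth$chains[[ch]]$fold_span
      ri <- model$atoms$resi[sel]
      p[ri < span[1] | ri > span[2]] <- tail_plddt
    }
    model$atoms$plddt[sel] <- p
  }
  n <- sum(lens)
  v <- matrix(inter_pae, n, n)
  ends <- cumsum(lens); starts <- c(1L, head(ends, -1) + 1L)
  for (k in seq_along(lens)) {
    idx <- seq(starts[k], ends[k])
    v[idx, idx] <- intra_pae
  }
  list(model = model, pae = hf_pae(v, stats::setNames(lens, chains)))
}

# fold-friendly background alphabet: no R/C/H/P, so implanted motifs,
# zinc sites and P-loops are the only ones possible or near-impossible
BACKGROUND_AA <- strsplit("ALEQVIFYSTNDGMKW", "")[[1]]

#' Synthesize a fixture sequence with implanted features
#'
#' Draws background residues from a fold-friendly alphabet (no Arg, Cys,
#' His, Pro) and implants the requested features at architecture-derived
#' positions; rejection sampling guarantees the implanted features are the
#' only matches reported by the scanners.
#'
#' @param arch an `hf_arch`
#' @param features list: `motif` (RxTxxxxD anchored at the L2 loop; TRUE
#'   also places the K for the RKTxxxxD variant when `rkt = TRUE`),
#'   `zz_sites` (C4 + C2H2 implanted in the N-flank), `ploop` (Walker A in
#'   the N-flank), `tail_sign` (+1/-1: charge the tail flanks), `tm`
#'   (hydrophobic stretch on the tm_segment flank), `basic_alpha1`
#'   (lysines on alpha1; default TRUE), `rkt` (default FALSE)
#' @param seed integer seed
#' @return list: `sequence`, `truth` (named list of implanted positions)
#' @export
synth_sequence_set <- function(arch, features = list(), seed = 1L) {
  f <- utils::modifyList(list(motif = TRUE, zz_sites = FALSE, ploop = FALSE,
                              tail_sign = NULL, tm = FALSE,
                              basic_alpha1 = TRUE, rkt = FALSE), features)
  tr <- arch_truth(arch)
  n <- arch_length(arch)
  nf <- flank_total(arch$n_flank); cf <- flank_total(arch$c_flank)
  if (f$zz_sites && nf < 60L)
    stop("zz_sites need an N-flank of at least 60 residues")
  if (f$ploop && nf < 10L) stop("ploop needs an N-flank")
  if (f$tm && arch$n_flank$kind != "tm_segment" && arch$c_flank$kind != "tm_segment")
    stop("tm feature needs a tm_segment flank")
  truth <- list()
  with_seed(seed, {
    for (attempt in 1:200) {
      s <- sample(BACKGROUND_AA, n, replace = TRUE)
      # keep the alpha1 face free of basics unless asked for
      a1pos <- seq(tr$alpha1[1], tr$alpha1[2])
      band <- seq(tr$alpha1[1], tr$alpha3[2])
      s[band][s[band] == "K"] <- "Q"
      if (f$basic_alpha1) {
        kpos <- a1pos[c(3, 7)]
        s[kpos] <- "K"
        truth$basic_alpha1 <- kpos
      }
      if (f$motif) {
        r <- tr$alpha2[2]           # R on the last alpha2 residue
        s[r] <- "R"; s[r + 2L] <- "T"; s[r + 7L] <- "D"
        if (f$rkt) s[r + 1L] <- "K"
        truth$motif_anchor <- r
      }
      if (f$zz_sites) {
        base <- 0L  # positions within the N-flank (domain occupies 1..len)
        c4 <- base + c(10L, 13L, 41L, 43L)
        c2h2_c <- base + c(26L, 31L); c2h2_h <- base + c(49L, 55L)
        s[c4] <- "C"; s[c2h2_c] <- "C"; s[c2h2_h] <- "H"
        truth$zz <- list(c4 = c4, c2h2 = c(c2h2_c, c2h2_h))
      }
      if (f$ploop) {
        p <- 3L
        s[p:(p + 7L)] <- c("G", "A", "S", "G", "V", "G", "K", "T")
        truth$ploop <- p
      }
      if (!is.null(f$tail_sign)) {
        aa <- if (f$tail_sign > 0) c("K", "R") else c("D", "E")
        for (side in c("n", "c")) {
          fl <- if (side == "n") arch$n_flank else arch$c_flank
          if (fl$kind == "charged_tail") {
            pos <- if (side == "n") seq_len(nf) else seq(n - cf + 1L, n)
            s[pos] <- sample(aa, length(pos), replace = TRUE)
            truth[[paste0("tail_", toupper(side))]] <- range(pos)
          }
        }
      }
      if (f$tm) {
        for (side in c("n", "c")) {
          fl <- if (side == "n") arch$n_flank else arch$c_flank
          if (fl$kind == "tm_segment") {
            pos <- if (side == "n") seq_len(nf) else seq(n - cf + 1L, n)
            s[pos] <- sample(c("L", "I", "V", "F", "A"), length(pos),
                             replace = TRUE, prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
            truth$tm <- range(pos)
          }
        }
      }
      seqstr <- paste(s, collapse = "")
      if (sequence_is_clean(seqstr, f, truth)) break
      if (attempt == 200) stop("rejection sampling failed to produce a clean sequence")
    }
  })
  list(sequence = seqstr, truth = truth)
}

# the implanted features must be the only scanner matches
sequence_is_clean <- function(seqstr, f, truth) {
  hits <- scan_l2_motif(seqstr)
  if (f$motif) {
    if (nrow(hits) != 1L || hits$anchor_position != truth$motif_anchor) return(FALSE)
  } else if (nrow(hits)) return(FALSE)
  zz <- detect_zinc_motifs(seqstr)
  if (f$zz_sites) {
    if (!length(zz)) return(FALSE)
    ok <- any(vapply(zz, function(h) identical(h$c4, truth$zz$c4) &&
                       identical(h$c2h2, truth$zz$c2h2), logical(1)))
    if (!ok) return(FALSE)
  } else if (length(zz)) return(FALSE)
  pl <- detect_ploop(seqstr)
  if (f$ploop) { if (!identical(pl, truth$ploop)) return(FALSE) }
  else if (length(pl)) return(FALSE)
  tm <- detect_transmembrane(seqstr)
  if (f$tm) {
    if (nrow(tm) != 1L) return(FALSE)
  } else if (nrow(tm)) return(FALSE)
  TRUE
}

#' Synthesize a multiple sequence alignment
#'
#' Conserved columns emit their fixed residue with probability 0.95 (the
#' rest uniform over the other 19); free columns are uniform over all 20.
#'
#' @param profile list of column specs: each either a single residue
#'   (conserved column) or NA (free column)
#' @param n_sequences number of rows (>= 2)
#' @param seed integer seed
#' @return character vector of aligned sequences
#' @export
synth_msa <- function(profile, n_sequences, seed = 1L) {
  if (n_sequences < 2L) stop("need at least 2 sequences")
  with_seed(seed, {
    cols <- lapply(profile, function(p) {
      if (is.na(p)) sample(AA20, n_sequences, replace = TRUE)
      else ifelse(stats::runif(n_sequences) < 0.95, p,
                  sample(setdiff(AA20, p), n_sequences, replace = TRUE))
    })
    apply(do.call(cbind, cols), 1, paste, collapse = "")
  })
}
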