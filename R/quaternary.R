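# Quaternary-topology classification and final category assignment.
#
# Multimer predictions are reduced to CA-CA interface contact maps; the
# topology rules mirror the defining structures of each histone category:
# the handshake dimer, the face-to-face (FtF) torus tetramer closed through
# both dimer ends (alpha3 + last 8 residues of alpha2), the coiled-coil
# 4-helix bundle, and C-terminal tetramerization without a bundle.

#' Inter-chain CA contact map
#'
#' All unordered chain-pair CA-CA contacts at or below `cutoff`. The default
#' 8 Angstrom is the standard coarse contact definition.
#'
#' @param model an `hf_structure` with at least 2 chains
#' @param cutoff distance cutoff in Angstrom
#' @return object of class `hf_contacts`: `pairs` data.frame (chain_a, res_a,
#'   chain_b, res_b, dist) with chain_a before chain_b in chain order, and
#'   `counts` data.frame of per-chain-pair contact counts
#' @export
find_interchain_contacts <- function(model, cutoff = 8.0) {
  chains <- hf_chains(model)
  if (length(chains) < 2L)
    stop("single-chain model: use the monomer path, contacts need >= 2 chains")
  pairs <- NULL
  for (i in seq_len(length(chains) - 1L)) {
    for (j in seq(i + 1L, length(chains))) {
      ca_i <- hf_ca(model, chains[i]); ca_j <- hf_ca(model, chains[j])
      xi <- as.matrix(ca_i[, c("x", "y", "z")])
      xj <- as.matrix(ca_j[, c("x", "y", "z")])
      d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * (xi %*% t(xj))
      d2[d2 < 0] <- 0
      hit <- which(sqrt(d2) <= cutoff, arr.ind = TRUE)
      if (nrow(hit)) {
        pairs <- rbind(pairs, data.frame(
          chain_a = chains[i], res_a = hit[, 1],
          chain_b = chains[j], res_b = hit[, 2],
          dist = sqrt(d2[hit]), stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(pairs)) pairs <- data.frame(chain_a = character(), res_a = integer(),
                                          chain_b = character(), res_b = integer(),
                                          dist = numeric(), stringsAsFactors = FALSE)
  counts <- if (nrow(pairs)) aggregate(list(n = pairs$res_a),
                                       by = list(chain_a = pairs$chain_a,
                                                 chain_b = pairs$chain_b), FUN = length)
            else data.frame(chain_a = character(), chain_b = character(), n = integer())
  structure(list(pairs = pairs, counts = counts, cutoff = cutoff),
            class = "hf_contacts")
}

# contacts between two chains restricted to residue position sets
contacts_between <- function(contacts, ca, cb, pos_a = NULL, pos_b = NULL) {
  p <- contacts$pairs
  fwd <- p$chain_a == ca & p$chain_b == cb
  rev <- p$chain_a == cb & p$chain_b == ca
  sub <- rbind(
    p[fwd, c("res_a", "res_b", "dist")],
    if (any(rev)) data.frame(res_a = p$res_b[rev], res_b = p$res_a[rev],
                             dist = p$dist[rev])
  )
  if (is.null(sub) || !nrow(sub)) return(sub[0, ])
  if (!is.null(pos_a)) sub <- sub[sub$res_a %in% pos_a, , drop = FALSE]
  if (!is.null(pos_b)) sub <- sub[sub$res_b %in% pos_b, , drop = FALSE]
  sub
}

# least-squares axis (first principal component) of a run of CA coords
helix_axis <- function(model, chain, positions) {
  ca <- hf_ca(model, chain)
  xyz <- as.matrix(ca[positions, c("x", "y", "z")])
  pc <- prcomp(xyz, center = TRUE)
  v <- pc$rotation[, 1]
  # orient N -> C
  if (sum((xyz[nrow(xyz), ] - xyz[1, ]) * v) < 0) v <- -v
  v
}

#' Detect the handshake histone dimer
#'
#' True when the two alpha2 helices share at least 10 inter-chain CA
#' contacts (8 Angstrom) and their axes cross at 15-60 degrees. In the
#' handshake the alpha1 and alpha3 helices sit on opposite faces; only the
#' alpha2 crossing is tested, which is what the fixture geometry makes
#' unambiguous.
#'
#' @param model a 2-chain `hf_structure`
#' @param anns named list of `hf_fold` annotations, one per chain
#' @param contacts optional precomputed [find_interchain_contacts()] map
#' @return list: `is_handshake`, `crossing_angle` (degrees), `n_a2_contacts`
#' @export
detect_handshake_dimer <- function(model, anns, contacts = NULL) {
  chains <- hf_chains(model)
  if (length(chains) != 2L)
    stop("handshake detection needs exactly 2 chains, got ", length(chains))
  for (ch in chains) if (is.null(anns[[ch]]))
    stop("missing fold annotation for chain ", ch)
  if (is.null(contacts)) contacts <- find_interchain_contacts(model)
  a2a <- fold_positions(anns[[chains[1]]], "alpha2")
  a2b <- fold_positions(anns[[chains[2]]], "alpha2")
  sub <- contacts_between(contacts, chains[1], chains[2], a2a, a2b)
  n <- nrow(sub)
  va <- helix_axis(model, chains[1], a2a)
  vb <- helix_axis(model, chains[2], a2b)
  ang <- acos(pmin(1, abs(sum(va * vb)))) * 180 / pi  # line-line angle, [0,90]
  list(is_handshake = n >= 10L && ang >= 15 && ang <= 60,
       crossing_angle = ang, n_a2_contacts = n)
}

#' Interface confidence from a PAE matrix
#'
#' Mean predicted aligned error over both off-diagonal blocks of a chain
#' pair (PAE is directional; the mean of the a->b and b->a blocks is the
#' symmetric aggregate). Interfaces with mean PAE strictly below 10 Angstrom
#' are high quality; a mean of exactly 10 is low.
#'
#' @param pae an `hf_pae`
#' @param chain_a,chain_b chain ids present in `pae$chain_spans`
#' @return list: `mean_interchain_pae` (Angstrom), `quality` ("high"/"low")
#' @export
interface_confidence <- function(pae, chain_a, chain_b) {
  for (ch in c(chain_a, chain_b)) if (is.null(pae$chain_spans[[ch]]))
    stop("chain not in PAE spans: ", ch)
  sa <- pae$chain_spans[[chain_a]]; sb <- pae$chain_spans[[chain_b]]
  ia <- seq(sa["start"] + 1L, sa["end"]); ib <- seq(sb["start"] + 1L, sb["end"])
  m <- mean(c(pae$values[ia, ib], pae$values[ib, ia]))
  list(mean_interchain_pae = m, quality = if (m < 10.0) "high" else "low")
}

# best pairing of 4 chains into 2 dimers by total alpha2<->alpha2 contacts
pair_dimers <- function(model, anns, contacts) {
  chains <- hf_chains(model)
  pairings <- list(
    list(c(1L, 2L), c(3L, 4L)), list(c(1L, 3L), c(2L, 4L)), list(c(1L, 4L), c(2L, 3L)))
  a2 <- lapply(chains, function(ch) fold_positions(anns[[ch]], "alpha2"))
  names(a2) <- chains
  score_pair <- function(idx) {
    nrow(contacts_between(contacts, chains[idx[1]], chains[idx[2]],
                          a2[[idx[1]]], a2[[idx[2]]]))
  }
  scores <- vapply(pairings, function(p) score_pair(p[[1]]) + score_pair(p[[2]]),
                   numeric(1))
  best <- pairings[[which.max(scores)]]  # ties: chain order (first pairing wins)
  list(dimers = lapply(best, function(idx) chains[idx]),
       a2_contacts = c(score_pair(best[[1]]), score_pair(best[[2]])))
}

#' Classify the tetramer quaternary topology
#'
#' Pairs the four chains into two handshake dimers (maximal alpha2-alpha2
#' contact count), then classifies the inter-dimer interfaces by the fold
#' elements that carry them:
#' * `ftf_torus` - exactly 2 inter-dimer interfaces, >= 60% of inter-dimer
#'   contacts on alpha3 or the last 8 residues of alpha2 (both dimer ends
#'   engage, closing a torus);
#' * `cc_bundle` - >= 60% of inter-dimer contacts on post-fold C-terminal
#'   residues and the C-terminal helices of all 4 chains mutually within
#'   12 Angstrom (coiled-coil bundle);
#' * `ctail_tetramer` - C-terminal dominance without bundle geometry;
#' * `open_stack` - a single FtF-style interface (nucleosomal-like stacking);
#' * `none` - anything else, including separated dimers.
#'
#' @param model a 4-chain `hf_structure`
#' @param anns named list of `hf_fold` annotations per chain
#' @param contacts optional precomputed contact map
#' @param pae optional `hf_pae`; when given, interface confidence is the
#'   mean PAE over the cross-dimer chain pairs that carry the decisive
#'   interfaces ("high" only if every such pair is below 10 Angstrom)
#' @param min_interface_contacts contacts required to count a chain pair as
#'   an interface (default 3)
#' @param dominance element-dominance fraction (default 0.6)
#' @return object of class `hf_topology`: `topology`, `interfaces`
#'   (data.frame chain_a, chain_b, n, n_ftf_style, n_post_fold),
#'   `confidence` ("high"/"low"/NA), `dimers`, `reason`
#' @export
classify_tetramer_topology <- function(model, anns, contacts = NULL, pae = NULL,
                                       min_interface_contacts = 3L,
                                       dominance = 0.6) {
  chains <- hf_chains(model)
  if (length(chains) != 4L) stop("tetramer topology needs 4 chains, got ",
                                 length(chains))
  if (is.null(contacts)) contacts <- find_interchain_contacts(model)
  no_ann <- chains[vapply(chains, function(ch) is.null(anns[[ch]]), logical(1))]
  if (length(no_ann))
    return(topology_call("none", reason = paste("no fold annotation for chain(s):",
                                                paste(no_ann, collapse = ","))))
  pairing <- pair_dimers(model, anns, contacts)
  if (any(pairing$a2_contacts == 0L))
    return(topology_call("none", reason = "chains not pairable into handshake dimers"))
  d1 <- pairing$dimers[[1]]; d2 <- pairing$dimers[[2]]
  # element position sets per chain
  ftf_set <- lapply(chains, function(ch)
    c(fold_positions(anns[[ch]], "alpha3"), fold_positions(anns[[ch]], "alpha2_last8")))
  post_set <- lapply(chains, function(ch) fold_positions(anns[[ch]], "post_fold"))
  names(ftf_set) <- names(post_set) <- chains
  cross <- expand.grid(a = d1, b = d2, stringsAsFactors = FALSE)
  iface <- do.call(rbind, lapply(seq_len(nrow(cross)), function(k) {
    ca <- cross$a[k]; cb <- cross$b[k]
    sub <- contacts_between(contacts, ca, cb)
    nf <- sum(sub$res_a %in% ftf_set[[ca]] & sub$res_b %in% ftf_set[[cb]])
    np <- sum(sub$res_a %in% post_set[[ca]] & sub$res_b %in% post_set[[cb]])
    data.frame(chain_a = ca, chain_b = cb, n = nrow(sub),
               n_ftf_style = nf, n_post_fold = np, stringsAsFactors = FALSE)
  }))
  n_inter <- sum(iface$n)
  active <- iface[iface$n >= min_interface_contacts, , drop = FALSE]
  topo <- "none"; reason <- ""
  if (n_inter == 0L) {
    reason <- "no inter-dimer contacts"
  } else {
    frac_ftf <- sum(iface$n_ftf_style) / n_inter
    frac_post <- sum(iface$n_post_fold) / n_inter
    bundle <- cterm_bundle(model, anns, chains)
    if (frac_post >= dominance && bundle) {
      topo <- "cc_bundle"
    } else if (frac_post >= dominance) {
      topo <- "ctail_tetramer"
    } else if (nrow(active) == 2L && frac_ftf >= dominance) {
      topo <- "ftf_torus"
    } else if (nrow(active) == 1L && frac_ftf >= dominance) {
      topo <- "open_stack"
    } else {
      reason <- sprintf("no dominant interface class (ftf %.2f, post-fold %.2f over %d interfaces)",
                        frac_ftf, frac_post, nrow(active))
    }
  }
  conf <- NA_character_
  if (!is.null(pae) && nrow(active)) {
    q <- vapply(seq_len(nrow(active)), function(k)
      interface_confidence(pae, active$chain_a[k], active$chain_b[k])$quality,
      character(1))
    conf <- if (all(q == "high")) "high" else "low"
  } else if (!is.null(pae)) {
    conf <- "low"
  }
  topology_call(topo, interfaces = iface, confidence = conf,
                dimers = list(d1, d2), reason = reason)
}

topology_call <- function(topology, interfaces = NULL, confidence = NA_character_,
                          dimers = NULL, reason = "") {
  structure(list(topology = topology, interfaces = interfaces,
                 confidence = confidence, dimers = dimers, reason = reason),
            class = "hf_topology")
}

#' @export
print.hf_topology <- function(x, ...) {
  cat(sprintf("<hf_topology> %s (confidence %s)%s\n", x$topology,
              x$confidence, if (nzchar(x$reason)) paste0(" - ", x$reason) else ""))
  invisible(x)
}

# post-fold C-terminal residues of all 4 chains mutually within 12 A
cterm_bundle <- function(model, anns, chains, mutual_cutoff = 12) {
  coords <- lapply(chains, function(ch) {
    pos <- fold_positions(anns[[ch]], "post_fold")
    if (!length(pos)) return(NULL)
    as.matrix(hf_ca(model, ch)[pos, c("x", "y", "z")])
  })
  if (any(vapply(coords, is.null, logical(1)))) return(FALSE)
  for (i in seq_len(3L)) for (j in seq(i + 1L, 4L)) {
    d2 <- outer(rowSums(coords[[i]]^2), rowSums(coords[[j]]^2), "+") -
      2 * coords[[i]] %*% t(coords[[j]])
    if (sqrt(max(0, min(d2))) > mutual_cutoff) return(FALSE)
  }
  TRUE
}

#' Flag fused flanking domains
#'
#' Flanking segments of at least 25 residues outside the fold span are
#' reported; a segment is `compact` (folded domain rather than extended
#' tail) when its CA radius of gyration is below 0.45 x (length x 1.5
#' Angstrom), i.e. well below the extent of an extended chain.
#'
#' @param model an `hf_structure`
#' @param ann `hf_fold` annotation of the chain
#' @param chain chain id (default the annotation's chain)
#' @return data.frame (side, start, end, length, rg, compact); zero rows
#'   when there is no qualifying flank
#' @export
detect_extra_domains <- function(model, ann, chain = ann$chain) {
  ca <- hf_ca(model, chain)
  out <- data.frame(side = character(), start = integer(), end = integer(),
                    length = integer(), rg = numeric(), compact = logical(),
                    stringsAsFactors = FALSE)
  for (side in c("N", "C")) {
    pos <- fold_positions(ann, if (side == "N") "pre_fold" else "post_fold")
    if (length(pos) < 25L) next
    xyz <- as.matrix(ca[pos, c("x", "y", "z")])
    rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
    out <- rbind(out, data.frame(
      side = side, start = min(pos), end = max(pos), length = length(pos),
      rg = rg, compact = rg < 0.45 * (length(pos) * 1.5),
      stringsAsFactors = FALSE))
  }
  out
}

#' Diameter of the DNA-wrapped tetramer
#'
#' Models DNA wrapped around the outside of a torus-shaped tetramer: the
#' maximal CA-CA extent within the torus plane (the plane orthogonal to the
#' smallest principal axis of the CA cloud) plus one DNA duplex diameter on
#' either side.
#'
#' @param model a 4-chain `hf_structure`
#' @param dna_diameter DNA duplex diameter in nm (default 2.0)
#' @return estimated wrapped diameter in nm
#' @export
estimate_wrapped_diameter <- function(model, dna_diameter = 2.0) {
  if (length(hf_chains(model)) < 4L) stop("wrapped-diameter model needs a tetramer")
  xyz <- as.matrix(hf_ca(model)[, c("x", "y", "z")])
  ctr <- sweep(xyz, 2, colMeans(xyz))
  if (nrow(unique(round(ctr, 6))) > 2L) {
    pc <- prcomp(ctr)
    ctr <- ctr %*% pc$rotation[, 1:2, drop = FALSE]  # project out torus axis
  }
  d2 <- outer(rowSums(ctr^2), rowSums(ctr^2), "+") - 2 * ctr %*% t(ctr)
  max_ext <- sqrt(max(0, max(d2)))
  max_ext / 10 + 2 * dna_diameter
}

#' Assign the final histone category
#'
#' First-match decision tree over fold family, quaternary topology, fused
#' domains, and sequence features. Any rule whose decisive evidence is a
#' multimer interface is skipped unless that interface is high confidence
#' (mean inter-chain PAE below 10 Angstrom); when every decisive interface
#' is low confidence the result is `undefined`.
#'
#' @param fold_family "nucleosomal", "alpha3", "ambiguous", or NA
#' @param dimer optional list from [detect_handshake_dimer()] augmented with
#'   `confidence` ("high"/"low"/NA) and optionally `dimerizing_ctail`
#' @param tetramer optional `hf_topology`
#' @param domains optional data.frame from [detect_extra_domains()]
#' @param seqfeat optional list with logical `has_zz`, `has_ploop`, `has_tm`
#'   and integer `n_basic_alpha1`, numeric `cterm_helix_len`
#' @return object of class `hf_category`: `category`, `evidence` (character
#'   vector of fired/considered rules), `confidence`, `rdgc_flag`
#' @export
assign_category <- function(fold_family, dimer = NULL, tetramer = NULL,
                            domains = NULL, seqfeat = NULL) {
  ev <- character()
  note <- function(...) ev <<- c(ev, sprintf(...))
  res <- function(category, confidence = "high", rdgc_flag = FALSE) {
    structure(list(category = category, evidence = ev, confidence = confidence,
                   rdgc_flag = rdgc_flag), class = "hf_category")
  }
  sf <- function(name, default) {
    v <- seqfeat[[name]]; if (is.null(v)) default else v
  }
  dim_high <- !is.null(dimer) && identical(dimer$confidence, "high")
  tet_high <- !is.null(tetramer) && identical(tetramer$confidence, "high")
  tet_topo <- if (!is.null(tetramer) && tet_high) tetramer$topology else "none"
  if (!is.null(tetramer) && !tet_high && tetramer$topology != "none")
    note("tetramer topology %s ignored: interface confidence not high",
         tetramer$topology)
  handshake <- !is.null(dimer) && isTRUE(dimer$is_handshake) && dim_high
  if (!is.null(dimer) && isTRUE(dimer$is_handshake) && !dim_high)
    note("handshake dimer ignored: interface confidence not high")
  if (is.na(fold_family) || !nzchar(fold_family)) {
    note("no histone fold detected")
    return(res("undefined", confidence = "low"))
  }
  n_dom <- function(min_len = 25L) {
    !is.null(domains) && nrow(domains) &&
      any(domains$side == "N" & domains$compact & domains$length >= min_len)
  }
  # (1) lost DNA binding, gained a transmembrane segment
  if (sf("n_basic_alpha1", NA_integer_) %in% 0L && isTRUE(sf("has_tm", FALSE))) {
    note("no basic residues on the alpha1 face and a transmembrane segment")
    return(res("transmembrane"))
  }
  if (fold_family == "alpha3") {
    if (n_dom() && isTRUE(sf("has_zz", FALSE))) {
      note("alpha3 fold with N-terminal compact domain carrying ZZ zinc sites")
      return(res("zz"))
    }
    if (n_dom(120L) && isTRUE(sf("has_ploop", FALSE))) {
      note("alpha3 fold with N-terminal compact domain >= 120 aa and P-loop motif")
      return(res("rab_gtpase"))
    }
    if (tet_topo %in% c("ctail_tetramer", "cc_bundle")) {
      note("alpha3 fold tetramerizing through the C-terminal domain (%s)", tet_topo)
      return(res("phage_like"))
    }
    if (tet_topo == "ftf_torus") {
      note("alpha3 fold closing a face-to-face torus tetramer")
      return(res("ftf"))
    }
    if (handshake) {
      note("alpha3 fold with a confident handshake dimer and no larger assembly")
      return(res("bacterial_dimer"))
    }
    note("alpha3 fold without usable multimer evidence")
    return(res("undefined", confidence = "low"))
  }
  if (fold_family == "nucleosomal") {
    if (tet_topo == "cc_bundle") {
      flag <- sf("cterm_helix_len", 0) >= 30
      note("nucleosomal fold with C-terminal coiled-coil bundle tetramer%s",
           if (flag) " (long C-helix: RdgC-like)" else "")
      return(res("coiled_coil", rdgc_flag = flag))
    }
    if (tet_topo == "ctail_tetramer") {
      note("nucleosomal fold with C-terminal tetramerization domain")
      return(res("mc_like"))
    }
    if (handshake && isTRUE(dimer$dimerizing_ctail)) {
      note("nucleosomal dimer with structured dimerizing C-terminal tail")
      return(res("ihf_like"))
    }
    if (tet_topo == "open_stack" || handshake) {
      note("nucleosomal fold stacking/dimerizing like nucleosomal histones")
      return(res("nucleosomal"))
    }
    if (is.null(dimer) && is.null(tetramer)) {
      note("nucleosomal fold; no multimer evidence")
      return(res("nucleosomal", confidence = "low"))
    }
    note("nucleosomal fold but all decisive interfaces low confidence")
    return(res("undefined", confidence = "low"))
  }
  note("ambiguous fold family")
  res("undefined", confidence = "low")
}

#' @export
print.hf_category <- function(x, ...) {
  cat(sprintf("<hf_category> %s (confidence %s)\n", x$category, x$confidence))
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

#' Detect a structured dimerizing C-terminal tail in a dimer
#'
#' IHF-related histones dimerize through a structured C-terminal tail: two
#' post-fold helices of each chain packing against the partner's. Requires
#' a predominantly helical post-fold region (at least half of its residues
#' assigned H; the two-helix hairpin often reads as one or two runs once
#' coordinate noise blurs the turn) and at least 5 inter-chain contacts
#' between the post-fold regions.
#'
#' @param model a 2-chain `hf_structure`
#' @param anns named list of `hf_fold` annotations
#' @param contacts optional contact map
#' @return logical
#' @export
detect_dimerizing_ctail <- function(model, anns, contacts = NULL) {
  chains <- hf_chains(model)
  if (length(chains) != 2L) stop("dimerizing C-tail check needs 2 chains")
  if (is.null(contacts)) contacts <- find_interchain_contacts(model)
  post <- lapply(chains, function(ch) fold_positions(anns[[ch]], "post_fold"))
  names(post) <- chains
  if (any(lengths(post) < 8L)) return(FALSE)
  helical <- vapply(chains, function(ch) {
    runs <- robust_runs(model, ch)
    covered <- sum(vapply(seq_len(nrow(runs)), function(k)
      length(intersect(seq(runs$start[k], runs$end[k]), post[[ch]])), integer(1)))
    covered >= 0.5 * length(post[[ch]])
  }, logical(1))
  if (!all(helical)) return(FALSE)
  nrow(contacts_between(contacts, chains[1], chains[2],
                        post[[chains[1]]], post[[chains[2]]])) >= 5L
}
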