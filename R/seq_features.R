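# Sequence-level annotation: L2 motifs, zinc sites, tails, transmembrane
# segments, alpha1-face basic residues, and conservation profiles.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

check_sequence <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(s), AA20)
  if (length(bad)) stop("non-amino-acid letters in sequence: ",
                        paste(bad, collapse = ", "))
  s
}

#' Scan for the L2 RxTxxxxD motif
#'
#' Reports every position i with R at i, T at i+2 and D at i+7 (the
#' conserved arginine/aspartate structure the L2 loop, the threonine binds
#' DNA). A lysine at i+1 upgrades the hit to the nucleosomal-type RKTxxxxD
#' variant. With `d_offset = 6` the shorter RxTxxxD spacing is scanned
#' instead.
#'
#' @param sequence amino-acid string (20-letter alphabet)
#' @param fold optional `hf_fold`; when given, hits whose T lies within L2
#'   plus/minus 2 residues are flagged `structurally_anchored`
#' @param d_offset offset of the aspartate from the arginine (default 7)
#' @return data.frame (pattern_name, anchor_position, pos_R, pos_T, pos_D,
#'   structurally_anchored), zero rows when nothing matches
#' @export
scan_l2_motif <- function(sequence, fold = NULL, d_offset = 7L) {
  s <- check_sequence(sequence)
  n <- length(s)
  out <- data.frame(pattern_name = character(), anchor_position = integer(),
                    pos_R = integer(), pos_T = integer(), pos_D = integer(),
                    structurally_anchored = logical(), stringsAsFactors = FALSE)
  if (n < d_offset + 1L) return(out)
  l2 <- if (!is.null(fold)) fold_positions(fold, "l2") else integer()
  anchor_band <- if (length(l2)) seq(min(l2) - 2L, max(l2) + 2L) else integer()
  for (i in seq_len(n - d_offset)) {
    if (s[i] == "R" && s[i + 2L] == "T" && s[i + d_offset] == "D") {
      name <- if (s[i + 1L] == "K") "RKTxxxxD" else "RxTxxxxD"
      if (d_offset == 6L) name <- sub("xD$", "D", name)
      out <- rbind(out, data.frame(
        pattern_name = name, anchor_position = i,
        pos_R = i, pos_T = i + 2L, pos_D = i + d_offset,
        structurally_anchored = (i + 2L) %in% anchor_band,
        stringsAsFactors = FALSE))
    }
  }
  out
}

#' Basic residues on the DNA-binding alpha1 face
#'
#' Lysines and arginines within alpha1, L1 and L2 (the DNA-binding face of
#' the handshake dimer). When a structure is supplied, buried residues
#' (more than 14 CA neighbors within 10 Angstrom) are excluded, keeping the
#' solvent-exposed candidates.
#'
#' @param sequence amino-acid string of the chain
#' @param fold `hf_fold` annotation
#' @param model optional `hf_structure` containing the chain (all chains are
#'   used for the neighbor count, so dimer burial counts too)
#' @param chain chain id in `model` (default the annotation's chain)
#' @return integer vector of 1-based positions
#' @export
find_basic_alpha1_residues <- function(sequence, fold, model = NULL,
                                       chain = fold$chain) {
  s <- check_sequence(sequence)
  pos <- sort(unique(c(fold_positions(fold, "alpha1"),
                       fold_positions(fold, "l1"),
                       fold_positions(fold, "l2"))))
  pos <- pos[pos <= length(s)]
  hits <- pos[s[pos] %in% c("K", "R")]
  if (!is.null(model) && length(hits)) {
    ca_all <- hf_ca(model)
    ca_ch <- hf_ca(model, chain)
    xyz_all <- as.matrix(ca_all[, c("x", "y", "z")])
    keep <- vapply(hits, function(p) {
      v <- as.numeric(ca_ch[p, c("x", "y", "z")])
      sum(sqrt(colSums((t(xyz_all) - v)^2)) <= 10) - 1L <= 14L
    }, logical(1))
    hits <- hits[keep]
  }
  hits
}

#' Annotate terminal tails
#'
#' Flanking segments of at least 5 residues outside the fold span that are
#' not compact fused domains. Net charge counts K/R as +1, D/E as -1, H as
#' 0 (neutral pH); the charge class is positive (negative) when the
#' per-residue net charge is at least +0.2 (at most -0.2). A tail is
#' disordered when its mean pLDDT is below 50 (AlphaFold "very low" band);
#' without a pLDDT track the disorder call is NA.
#'
#' @param sequence amino-acid string
#' @param fold `hf_fold` annotation
#' @param plddt optional per-residue pLDDT vector (0-100)
#' @param domains optional [detect_extra_domains()] table; compact domains
#'   are not reported as tails
#' @return data.frame (terminus, start, end, length, net_charge, mean_plddt,
#'   disordered, charge_class)
#' @export
detect_tails <- function(sequence, fold, plddt = NULL, domains = NULL) {
  s <- check_sequence(sequence)
  out <- data.frame(terminus = character(), start = integer(), end = integer(),
                    length = integer(), net_charge = numeric(),
                    mean_plddt = numeric(), disordered = logical(),
                    charge_class = character(), stringsAsFactors = FALSE)
  spans <- list(
    N = if (fold$fold_span["start"] > 1L) c(1L, fold$fold_span["start"] - 1L) else NULL,
    C = if (fold$fold_span["end"] < length(s)) c(fold$fold_span["end"] + 1L, length(s)) else NULL)
  for (term in c("N", "C")) {
    sp <- spans[[term]]
    if (is.null(sp) || sp[2] - sp[1] + 1L < 5L) next
    if (!is.null(domains) && nrow(domains) &&
        any(domains$side == term & domains$compact)) next
    pos <- seq(sp[1], sp[2])
    q <- sum(s[pos] %in% c("K", "R")) - sum(s[pos] %in% c("D", "E"))
    frac <- q / length(pos)
    mp <- if (!is.null(plddt)) mean(plddt[pos]) else NA_real_
    out <- rbind(out, data.frame(
      terminus = term, start = sp[1], end = sp[2], length = length(pos),
      net_charge = q, mean_plddt = mp,
      disordered = if (is.na(mp)) NA else mp < 50,
      charge_class = if (frac >= 0.2) "positive" else if (frac <= -0.2) "negative" else "neutral",
      stringsAsFactors = FALSE))
  }
  out
}

#' Detect ZZ-type zinc-binding sites (C4 + C2H2)
#'
#' Searches for the interleaved residue arrangement of ZZ-type zinc
#' fingers: along the sequence C1-C2 (first half of the C4 site), C3-C4
#' (the C2H2 cysteines), C5-C6 (second half of the C4 site), then H1-H2
#' (the C2H2 histidines), with gaps C1-C2 of 1-4, C3-C4 of 2-6, C5-C6 of
#' 1-6 and H1-H2 of 1-7 residues, the whole site within a 60-residue
#' window. The C4 site is {C1, C2, C5, C6}; the C2H2 site is
#' {C3, C4, H1, H2}. With a structure, sites whose side-chain proxies
#' (CB, CA for Gly) are all pairwise within 8 Angstrom are flagged
#' `spatially_clustered`.
#'
#' @param sequence amino-acid string
#' @param model optional `hf_structure`
#' @param chain chain id in `model`
#' @return list of hits; each hit is a list with `c4` (4 positions), `c2h2`
#'   (4 positions), `window` (span), `spatially_clustered` (logical or NA)
#' @export
detect_zinc_motifs <- function(sequence, model = NULL, chain = NULL) {
  s <- check_sequence(sequence)
  cys <- which(s == "C"); his <- which(s == "H")
  hits <- list()
  if (length(cys) < 6L || length(his) < 2L) return(hits)
  gap_ok <- function(a, b, lo, hi) { g <- b - a - 1L; g >= lo && g <= hi }
  for (i1 in seq_along(cys)) for (i2 in seq_along(cys)) {
    if (i2 <= i1 || !gap_ok(cys[i1], cys[i2], 1L, 4L)) next
    for (i3 in seq_along(cys)) for (i4 in seq_along(cys)) {
      if (i3 <= i2 || i4 <= i3) next
      if (!gap_ok(cys[i3], cys[i4], 2L, 6L)) next
      for (i5 in seq_along(cys)) for (i6 in seq_along(cys)) {
        if (i5 <= i4 || i6 <= i5) next
        if (!gap_ok(cys[i5], cys[i6], 1L, 6L)) next
        for (h1 in seq_along(his)) for (h2 in seq_along(his)) {
          if (h2 <= h1) next
          if (his[h1] <= cys[i6] || !gap_ok(his[h1], his[h2], 1L, 7L)) next
          if (his[h2] - cys[i1] + 1L > 60L) next
          hits[[length(hits) + 1L]] <- list(
            c4 = cys[c(i1, i2, i5, i6)],
            c2h2 = c(cys[c(i3, i4)], his[c(h1, h2)]),
            window = c(cys[i1], his[h2]),
            spatially_clustered = NA)
        }
      }
    }
  }
  if (!length(hits)) return(hits)
  # drop hits nested in a wider assignment over the same window start
  if (!is.null(model)) {
    if (is.null(chain)) chain <- hf_chains(model)[1]
    ca <- hf_ca(model, chain)
    atoms <- model$atoms[model$atoms$chain == chain, ]
    proxy <- function(p) {
      cb <- atoms[atoms$resi == ca$resi[p] & atoms$atom == "CB", c("x", "y", "z")]
      if (nrow(cb)) as.numeric(cb[1, ]) else as.numeric(ca[p, c("x", "y", "z")])
    }
    for (k in seq_along(hits)) {
      clus <- vapply(list(hits[[k]]$c4, hits[[k]]$c2h2), function(site) {
        pts <- do.call(rbind, lapply(site, proxy))
        all(dist(pts) < 8)
      }, logical(1))
      hits[[k]]$spatially_clustered <- all(clus)
    }
  }
  hits
}

#' P-loop (Walker A) motif scan
#'
#' GxxxxGK(S/T), the phosphate-binding loop of Ras-family GTPases; used to
#' recognize the fused Rab-GTPase domain of Lokiarchaeal histones.
#'
#' @param sequence amino-acid string
#' @return integer vector of 1-based positions of the first G of each match
#' @export
detect_ploop <- function(sequence) {
  s <- paste(check_sequence(sequence), collapse = "")
  m <- gregexpr("(?=G....GK[ST])", s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Transmembrane segment detection (Kyte-Doolittle)
#'
#' Windowed mean hydropathy (window 19); maximal runs of consecutive
#' windows with mean above 1.6 are merged and reported as segments (the
#' union of a run of windows always spans at least 19 residues).
#'
#' @param sequence amino-acid string of length >= 19
#' @param window window size (default 19)
#' @param threshold hydropathy threshold (default 1.6)
#' @return data.frame (start, end); zero rows when no segment qualifies
#' @export
detect_transmembrane <- function(sequence, window = 19L, threshold = 1.6) {
  s <- check_sequence(sequence)
  n <- length(s)
  if (n < window) stop("sequence shorter than the hydropathy window (", window, ")")
  h <- KYTE_DOOLITTLE[s]
  cs <- c(0, cumsum(h))
  wm <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  pass <- wm > threshold
  out <- data.frame(start = integer(), end = integer())
  if (!any(pass)) return(out)
  r <- rle(pass)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    out <- rbind(out, data.frame(start = starts[k], end = ends[k] + window - 1L))
  }
  out
}

#' Column-wise conservation profile of an alignment
#'
#' Per column: amino-acid frequencies with a pseudocount of 0.5 per amino
#' acid over the non-gap symbols, and information content
#' log2(20) - H(frequencies) in bits (the height of a sequence-logo
#' column). Columns with more than 50% gaps are gap columns and map to no
#' reference position; reference positions are mapped against the first
#' sequence's ungapped coordinates.
#'
#' @param msa character vector of aligned sequences (equal lengths; gaps
#'   "-" or "."), or a character matrix (rows = sequences)
#' @param pseudocount per-amino-acid pseudocount (default 0.5)
#' @return object of class `hf_profile`: data.frame `columns` with
#'   `column`, `reference_position` (NA for gap columns), `gap_fraction`,
#'   `ic` (bits), and a 20-column frequency matrix `freq`
#' @export
conservation_profile <- function(msa, pseudocount = 0.5) {
  if (is.matrix(msa)) msa <- apply(msa, 1, paste, collapse = "")
  if (length(msa) < 2L) stop("alignment needs at least 2 sequences")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("ragged alignment: row lengths ",
                                       paste(unique(lens), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  m[m == "."] <- "-"
  ncol_aln <- ncol(m)
  ref <- cumsum(m[1, ] != "-")
  freq <- matrix(NA_real_, ncol_aln, 20, dimnames = list(NULL, AA20))
  ic <- numeric(ncol_aln); gapf <- numeric(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    col <- m[, j]
    gapf[j] <- mean(col == "-")
    counts <- table(factor(col[col != "-"], levels = AA20))
    f <- (as.numeric(counts) + pseudocount) / (sum(counts) + 20 * pseudocount)
    freq[j, ] <- f
    ic[j] <- log2(20) + sum(f * log2(f))
  }
  ic <- pmax(ic, 0)
  columns <- data.frame(
    column = seq_len(ncol_aln),
    reference_position = ifelse(gapf > 0.5 | m[1, ] == "-", NA_integer_, ref),
    gap_fraction = gapf, ic = ic)
  structure(list(columns = columns, freq = freq), class = "hf_profile")
}

#' Export a conservation profile as a logo table
#' @param profile an `hf_profile`
#' @param path output TSV path (position, 20 frequencies, IC)
#' @return invisibly, `path`
#' @export
write_profile <- function(profile, path) {
  tab <- cbind(profile$columns[, c("column", "reference_position")],
               as.data.frame(profile$freq),
               ic = profile$columns$ic)
  utils::write.table(format(tab, digits = 8), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- sequence / alignment IO ----------------------------------------------

#' Read sequences from FASTA
#' @param path FASTA file
#' @return named character vector of sequences (names = first header token)
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "[[:space:]]+"), `[`, character(1), 1)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output path
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(unlist(seqs)), path, width = 60L)
  invisible(path)
}

#' Read a multiple sequence alignment (FASTA or Stockholm)
#' @param path alignment file; Stockholm recognized by the "# STOCKHOLM"
#'   header line, anything else parsed as FASTA
#' @return named character vector of aligned rows
#' @export
read_msa <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^# STOCKHOLM", first)) read_stockholm(path) else read_fasta(path)
}

read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|//)", lines) & nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad)) stop("malformed Stockholm row: ", lines[bad[1]])
  ids <- vapply(toks, `[`, character(1), 1)
  seqs <- vapply(toks, `[`, character(1), 2)
  out <- tapply(seqs, factor(ids, levels = unique(ids)), paste, collapse = "")
  structure(as.character(out), names = names(out))
}
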