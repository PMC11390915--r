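# Structure containers and readers/writers for predicted models.
#
# A structure is stored as a flat atom table; per-residue confidence (pLDDT,
# 0-100) travels in the B-factor column as AlphaFold writes it.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- structure(names(AA_THREE_TO_ONE), names = unname(AA_THREE_TO_ONE))

#' Construct a structure model from an atom table
#'
#' The universal input record of the package: an ordered atom table covering
#' one or more chains, each residue carrying at least a CA atom and a pLDDT
#' value (B-factor column, 0-100 scale).
#'
#' @param atoms data.frame with columns `chain` (character), `resi`
#'   (integer, 1-based author numbering), `resn` (3-letter residue code),
#'   `atom` (atom name, e.g. "CA"), `x`, `y`, `z` (Angstrom), `plddt`
#'   (numeric, 0-100).
#' @return An object of class `hf_structure`.
#' @details Invariants enforced: residue indices strictly increasing within a
#'   chain, every residue has a CA atom, pLDDT within `[0, 100]`, finite
#'   coordinates. A model whose pLDDT values are all at or below 1 triggers a
#'   warning (possible 0-1 scale) but is never rescaled.
#' @export
hf_structure <- function(atoms) {
  need <- c("chain", "resi", "resn", "atom", "x", "y", "z", "plddt")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$chain <- as.character(atoms$chain)
  atoms$resi <- as.integer(atoms$resi)
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates")
  if (any(atoms$resi < 1L)) stop("residue indices must be >= 1")
  if (any(atoms$plddt < 0 | atoms$plddt > 100, na.rm = TRUE))
    stop("pLDDT outside [0, 100]")
  for (ch in unique(atoms$chain)) {
    ri <- atoms$resi[atoms$chain == ch]
    if (is.unsorted(unique(ri), strictly = TRUE) && any(diff(unique(ri)) <= 0))
      stop("residue indices not strictly increasing in chain ", ch)
    ca <- unique(atoms$resi[atoms$chain == ch & atoms$atom == "CA"])
    if (!setequal(unique(ri), ca))
      stop("chain ", ch, ": residues without a CA atom")
  }
  if (all(atoms$plddt <= 1, na.rm = TRUE))
    warning("all pLDDT values <= 1: input may be on a 0-1 scale (kept unchanged)")
  structure(list(atoms = atoms), class = "hf_structure")
}

#' @export
print.hf_structure <- function(x, ...) {
  ch <- hf_chains(x)
  n <- vapply(ch, function(c) nrow(hf_ca(x, c)), integer(1))
  cat("<hf_structure> ", length(ch), " chain(s): ",
      paste0(ch, " (", n, " res)", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Chain identifiers of a structure, in file order
#' @param model an `hf_structure`
#' @return character vector of chain ids
#' @export
hf_chains <- function(model) unique(model$atoms$chain)

#' CA records of a structure
#'
#' @param model an `hf_structure`
#' @param chain optional chain id; default all chains
#' @return data.frame with columns chain, resi, resn, x, y, z, plddt
#'   (one row per residue, chain/file order)
#' @export
hf_ca <- function(model, chain = NULL) {
  a <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  if (!is.null(chain)) {
    if (!all(chain %in% a$chain)) stop("chain not present: ",
                                       paste(setdiff(chain, a$chain), collapse = ","))
    a <- a[a$chain %in% chain, , drop = FALSE]
  }
  rownames(a) <- NULL
  a[, c("chain", "resi", "resn", "x", "y", "z", "plddt")]
}

#' One-letter sequence of a chain
#' @param model an `hf_structure`
#' @param chain chain id
#' @return single string; unknown residue codes become "X"
#' @export
hf_sequence <- function(model, chain) {
  ca <- hf_ca(model, chain)
  one <- AA_THREE_TO_ONE[ca$resn]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

#' Apply a rigid transform to a structure
#' @param model an `hf_structure`
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 vector (Angstrom)
#' @return transformed `hf_structure`
#' @export
hf_transform <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  out <- model
  out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]; out$atoms$z <- xyz[, 3]
  out
}

# ---- readers / writers -----------------------------------------------------

#' Read a predicted structure (PDB or mmCIF)
#'
#' Reads the first model of a coordinate file. The B-factor column is mapped
#' unchanged to `plddt` (AlphaFold convention, 0-100). Residues lacking a CA
#' atom are dropped with a warning. Only the first alternate location is
#' kept; insertion codes are rejected (predicted models never contain them).
#'
#' @param path file path
#' @param format "pdb", "mmcif", or "auto" (by extension; `.cif`/`.mmcif`
#'   mean mmCIF, anything else PDB)
#' @return an [hf_structure()]
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- if (format == "pdb") parse_pdb_atoms(path) else parse_mmcif_atoms(path)
  if (nrow(atoms) == 0L) stop("empty model in ", path)
  # drop residues lacking CA
  key <- paste(atoms$chain, atoms$resi)
  cakey <- unique(key[atoms$atom == "CA"])
  drop <- !(key %in% cakey)
  if (any(drop)) {
    warning(sum(!duplicated(key[drop])), " residue(s) without CA dropped from ", path)
    atoms <- atoms[!drop, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no residues with CA atoms in ", path)
  hf_structure(atoms)
}

parse_pdb_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- startsWith(lines, "ATOM  ")
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm)) keep[seq_along(lines) > endm[1]] <- FALSE
  lines <- lines[keep]
  if (!length(lines)) return(empty_atoms())
  fw <- function(l, a, b) substr(l, a, b)
  altloc <- trimws(fw(lines, 17, 17))
  icode <- trimws(fw(lines, 27, 27))
  if (any(icode != ""))
    stop("insertion codes are not supported (line with iCode '", icode[icode != ""][1], "')")
  xs <- suppressWarnings(as.numeric(fw(lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(fw(lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(fw(lines, 47, 54)))
  bs <- suppressWarnings(as.numeric(fw(lines, 61, 66)))
  ri <- suppressWarnings(as.integer(fw(lines, 23, 26)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs) | is.na(ri))
  if (length(bad))
    stop("unparsable ATOM record at line: ", lines[bad[1]])
  atoms <- data.frame(
    chain = trimws(fw(lines, 22, 22)),
    resi = ri,
    resn = trimws(fw(lines, 18, 20)),
    atom = trimws(fw(lines, 13, 16)),
    x = xs, y = ys, z = zs,
    plddt = ifelse(is.finite(bs), bs, 0),
    altloc = altloc,
    stringsAsFactors = FALSE
  )
  drop_extra_altlocs(atoms)
}

# keep the first altloc seen per (chain, resi, atom)
drop_extra_altlocs <- function(atoms) {
  key <- paste(atoms$chain, atoms$resi, atoms$atom)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  atoms
}

empty_atoms <- function() {
  data.frame(chain = character(), resi = integer(), resn = character(),
             atom = character(), x = numeric(), y = numeric(), z = numeric(),
             plddt = numeric(), stringsAsFactors = FALSE)
}

# minimal atom_site loop reader; auth_* numbering wins over label_*
parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^_atom_site\\.", lines, value = TRUE)
  if (!length(hdr)) stop("no _atom_site loop found in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(hdr))
  first <- grep("^_atom_site\\.", lines)[1]
  last_hdr <- first + length(hdr) - 1L
  body <- character()
  for (i in seq(last_hdr + 1L, length(lines))) {
    l <- lines[i]
    if (grepl("^(#|loop_|_[A-Za-z])", l) || !nzchar(trimws(l))) break
    body <- c(body, l)
  }
  if (!length(body)) stop("empty atom_site loop in ", path)
  toks <- strsplit(trimws(body), "[[:space:]]+")
  nbad <- which(lengths(toks) != length(fields))
  if (length(nbad))
    stop("malformed atom_site row ", nbad[1], " in ", path)
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  pick <- function(a, b) if (a %in% fields) m[, a] else m[, b]
  grp <- if ("group_PDB" %in% fields) m[, "group_PDB"] else rep("ATOM", nrow(m))
  keep <- grp == "ATOM"
  if ("pdbx_PDB_model_num" %in% fields && any(keep)) {
    mn <- m[, "pdbx_PDB_model_num"]
    keep <- keep & mn == mn[which(keep)[1]]
  }
  ic <- if ("pdbx_PDB_ins_code" %in% fields) m[, "pdbx_PDB_ins_code"] else rep("?", nrow(m))
  if (any(keep & !(ic %in% c("?", ".", ""))))
    stop("insertion codes are not supported (mmCIF)")
  atoms <- data.frame(
    chain = pick("auth_asym_id", "label_asym_id")[keep],
    resi = as.integer(pick("auth_seq_id", "label_seq_id")[keep]),
    resn = pick("auth_comp_id", "label_comp_id")[keep],
    atom = gsub('"', "", pick("auth_atom_id", "label_atom_id")[keep]),
    x = as.numeric(m[keep, "Cartn_x"]),
    y = as.numeric(m[keep, "Cartn_y"]),
    z = as.numeric(m[keep, "Cartn_z"]),
    plddt = if ("B_iso_or_equiv" %in% fields) as.numeric(m[keep, "B_iso_or_equiv"]) else 0,
    altloc = if ("label_alt_id" %in% fields) m[keep, "label_alt_id"] else "",
    stringsAsFactors = FALSE
  )
  if (any(is.na(atoms$resi)) || any(!is.finite(atoms$x)))
    stop("unparsable numeric field in atom_site loop of ", path)
  drop_extra_altlocs(atoms)
}

#' Write a structure to PDB or mmCIF
#'
#' pLDDT is written to the B-factor column with 2 decimals; files round-trip
#' through [read_structure()] with coordinates preserved to 1e-3 Angstrom.
#'
#' @param model an `hf_structure`
#' @param path output path
#' @param format "pdb" or "mmcif"
#' @return invisibly, `path`
#' @export
write_structure <- function(model, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- model$atoms
  if (nrow(a) == 0L) stop("refusing to write an empty model")
  if (format == "pdb") {
    lines <- character()
    serial <- 0L
    for (ch in hf_chains(model)) {
      sub <- a[a$chain == ch, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        serial <- serial + 1L
        an <- sub$atom[i]
        # column 13-16: names < 4 chars start at column 14
        anf <- if (nchar(an) >= 4L) sprintf("%-4s", an) else sprintf(" %-3s", an)
        lines <- c(lines, sprintf(
          "ATOM  %5d %s%s%3s %1s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, anf, " ", sub$resn[i], ch, sub$resi[i], " ",
          sub$x[i], sub$y[i], sub$z[i], 1.0, sub$plddt[i],
          substr(gsub("[0-9]", "", an), 1, 1)))
      }
      serial <- serial + 1L
      lines <- c(lines, sprintf("TER   %5d      %3s %1s%4d",
                                serial %% 100000L,
                                sub$resn[nrow(sub)], ch, sub$resi[nrow(sub)]))
    }
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_histofold", "#", "loop_",
             paste0("_atom_site.",
                    c("group_PDB", "id", "auth_atom_id", "auth_comp_id",
                      "auth_asym_id", "auth_seq_id", "Cartn_x", "Cartn_y",
                      "Cartn_z", "B_iso_or_equiv", "pdbx_PDB_model_num")))
    rows <- sprintf("ATOM %d %s %s %s %d %.3f %.3f %.3f %.2f 1",
                    seq_len(nrow(a)), a$atom, a$resn, a$chain, a$resi,
                    a$x, a$y, a$z, a$plddt)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

# ---- PAE -------------------------------------------------------------------

#' Construct a PAE matrix object
#'
#' @param values square numeric matrix of predicted aligned errors (Angstrom);
#'   kept asymmetric (PAE is directional), consumers decide aggregation.
#' @param chain_lengths named integer vector, chain id -> residue count, in
#'   prediction order; must sum to `nrow(values)`.
#' @return object of class `hf_pae` with fields `values` and `chain_spans`
#'   (named list of 0-based half-open `(start, end)` spans tiling `[0, N)`).
#' @export
hf_pae <- function(values, chain_lengths) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("PAE matrix is not square: ",
                                         nrow(values), "x", ncol(values))
  if (any(values < 0)) stop("PAE values must be >= 0")
  if (is.null(names(chain_lengths)))
    names(chain_lengths) <- LETTERS[seq_along(chain_lengths)]
  if (sum(chain_lengths) != nrow(values))
    stop("chain lengths sum to ", sum(chain_lengths),
         " but PAE matrix has ", nrow(values), " rows")
  ends <- cumsum(chain_lengths)
  starts <- c(0L, ends[-length(ends)])
  spans <- Map(function(s, e) c(start = as.integer(s), end = as.integer(e)),
               starts, ends)
  names(spans) <- names(chain_lengths)
  structure(list(values = values, chain_spans = spans), class = "hf_pae")
}

#' Read an AlphaFold-style PAE JSON file
#'
#' Accepts the `predicted_aligned_error` key (ColabFold/AFDB dialect) or the
#' fallback key `pae`; a top-level one-element list wrapper is unwrapped.
#'
#' @param path JSON file path
#' @param chain_lengths integer vector (optionally named) of per-chain
#'   residue counts in prediction order
#' @return an [hf_pae()]
#' @export
read_pae <- function(path, chain_lengths) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.data.frame(obj)) obj <- as.list(obj)
  if (is.list(obj) && is.null(names(obj)) && length(obj) == 1L) obj <- obj[[1]]
  key <- intersect(c("predicted_aligned_error", "pae"), names(obj))
  if (!length(key)) stop("no 'predicted_aligned_error' (or 'pae') key in ", path)
  v <- obj[[key[1]]]
  if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
  hf_pae(as.matrix(v), chain_lengths)
}

#' Write a PAE matrix as AlphaFold-style JSON
#' @param pae an `hf_pae`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_pae <- function(pae, path) {
  jsonlite::write_json(list(predicted_aligned_error = pae$values),
                       path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

# ---- superposition ---------------------------------------------------------

#' Least-squares rigid CA superposition (Kabsch)
#'
#' Superposes the mobile model onto the reference over paired CA atoms and
#' returns the minimum least-squares RMSD together with the optimal rigid
#' transform (proper rotation; reflections excluded).
#'
#' @param mobile,reference `hf_structure` objects
#' @param pairing "by_index" pairs the i-th chain of `mobile` with the i-th
#'   chain of `reference` and intersects residue indices within each pair;
#'   "by_chain_map" uses `chain_map`.
#' @param chain_map named character vector, mobile chain -> reference chain
#' @return list with `rmsd` (Angstrom), `rotation` (3x3), `translation`
#'   (length 3, applied after rotation), `n_pairs`.
#' @export
superpose_ca <- function(mobile, reference,
                         pairing = c("by_index", "by_chain_map"),
                         chain_map = NULL) {
  pairing <- match.arg(pairing)
  mch <- hf_chains(mobile); rch <- hf_chains(reference)
  if (pairing == "by_index") {
    k <- min(length(mch), length(rch))
    chain_map <- structure(rch[seq_len(k)], names = mch[seq_len(k)])
  } else if (is.null(chain_map)) stop("chain_map required for by_chain_map")
  P <- NULL; Q <- NULL
  for (mc in names(chain_map)) {
    ca_m <- hf_ca(mobile, mc); ca_r <- hf_ca(reference, chain_map[[mc]])
    common <- intersect(ca_m$resi, ca_r$resi)
    if (!length(common)) next
    P <- rbind(P, as.matrix(ca_m[match(common, ca_m$resi), c("x", "y", "z")]))
    Q <- rbind(Q, as.matrix(ca_r[match(common, ca_r$resi), c("x", "y", "z")]))
  }
  if (is.null(P) || nrow(P) == 0L) stop("no common residues under the pairing")
  if (nrow(P) < 3L) stop("need at least 3 paired CA atoms, got ", nrow(P))
  kabsch(P, Q)
}

# optimal proper rotation mapping P onto Q (row = point)
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cq - R %*% cp),
       n_pairs = nrow(P))
}
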