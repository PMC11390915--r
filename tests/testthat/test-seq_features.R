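# brute-force motif oracle: literal scan over all start positions
brute_motif <- function(s, d_offset = 7L) {
  v <- strsplit(s, "")[[1]]
  out <- integer()
  for (i in seq_len(max(0L, length(v) - d_offset))) {
    if (v[i] == "R" && v[i + 2L] == "T" && v[i + d_offset] == "D")
      out <- c(out, i)
  }
  out
}

test_that("L2 motif scan finds RxTxxxxD and its RKT variant", {
  hits <- scan_l2_motif("MARVTQQQADKL")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$anchor_position, 3L)
  expect_identical(hits$pattern_name, "RxTxxxxD")
  expect_equal(nrow(scan_l2_motif("AAAAAAAA")), 0L)
  # K at R+1 upgrades the hit
  up <- scan_l2_motif("MARKTQQQADKL")
  expect_identical(up$pattern_name, "RKTxxxxD")
  # configurable shorter spacing variant (RxTxxxD)
  short <- scan_l2_motif("MARVTQQQDAA", d_offset = 6L)
  expect_equal(short$anchor_position, 3L)
  expect_error(scan_l2_motif("ARB"), "non-amino-acid")
})

test_that("motif scan equals the brute-force oracle on random sequences", {
  withr::local_seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:60) {
    s <- paste(sample(aas, 80, replace = TRUE), collapse = "")
    expect_equal(scan_l2_motif(s)$anchor_position, brute_motif(s))
  }
})

test_that("motif hits anchor structurally when T falls in L2", {
  # synthetic stand-in with the published FtF layout: R47, T49, D54
  s <- strsplit(strrep("A", 60), "")[[1]]
  s[47] <- "R"; s[49] <- "T"; s[54] <- "D"
  fold <- make_fold(a1 = c(5, 15), a2 = c(19, 46), a3 = c(50, 53), n_res = 60)
  hits <- scan_l2_motif(paste(s, collapse = ""), fold)
  expect_equal(hits$anchor_position, 47L)
  expect_true(hits$structurally_anchored)  # T49 within L2 (47..49) +/- 2
  # same sequence without a fold: hit reported, anchor flag FALSE
  expect_false(scan_l2_motif(paste(s, collapse = ""))$structurally_anchored)
})

test_that("basic alpha1-face residues are reported and burial-filtered", {
  fx <- fx_nuc_monomer()
  ann <- detect_histone_fold(fx$model, "A")
  s <- strsplit(strrep("A", ann$n_res), "")[[1]]
  a1 <- histofold:::fold_positions(ann, "alpha1")
  s[a1[c(3, 7)]] <- "K"
  pos <- find_basic_alpha1_residues(paste(s, collapse = ""), ann)
  expect_equal(pos, a1[c(3, 7)])
  expect_equal(length(find_basic_alpha1_residues(strrep("A", ann$n_res), ann)), 0L)
  # burial filter: neighbor count oracle on a dense synthetic cluster
  xyz <- rbind(expand.grid(x = seq(0, 9, 3), y = seq(0, 9, 3), z = seq(0, 6, 3)))
  m <- ca_model(as.matrix(xyz), resn = "LYS")
  ann2 <- make_fold(a1 = c(1, 11), a2 = c(15, 43), a3 = c(47, 56),
                    n_res = nrow(xyz))
  kept <- find_basic_alpha1_residues(strrep("K", nrow(xyz)), ann2, m, "A")
  nb <- vapply(seq_len(nrow(xyz)), function(i)
    sum(sqrt(colSums((t(as.matrix(xyz)) - as.numeric(xyz[i, ]))^2)) <= 10) - 1L,
    integer(1))
  expect_setequal(kept, intersect(c(1:14, 44:46), which(nb <= 14)))
})

test_that("tails are annotated with charge class and disorder", {
  fold <- make_fold(a1 = c(21, 31), a2 = c(35, 63), a3 = c(67, 76), n_res = 88)
  s <- paste0(strrep("E", 20), strrep("A", 56), strrep("K", 12))
  plddt <- c(rep(30, 20), rep(90, 56), rep(85, 12))
  tails <- detect_tails(s, fold, plddt)
  expect_equal(nrow(tails), 2L)
  nt <- tails[tails$terminus == "N", ]
  expect_equal(nt$length, 20L); expect_equal(nt$net_charge, -20)
  expect_true(nt$disordered); expect_identical(nt$charge_class, "negative")
  ct <- tails[tails$terminus == "C", ]
  expect_equal(ct$net_charge, 12); expect_identical(ct$charge_class, "positive")
  expect_false(ct$disordered)
  # a 3-residue flank is not a tail
  f2 <- make_fold(a1 = c(4, 14), a2 = c(18, 46), a3 = c(50, 59), n_res = 59)
  expect_equal(nrow(detect_tails(strrep("A", 59), f2)), 0L)
  # without pLDDT the disorder call is NA
  expect_true(is.na(detect_tails(s, fold)$disordered[1]))
})

test_that("net charge is additive and reversal-invariant", {
  qof <- function(s) {
    f <- make_fold(a1 = c(nchar(s) + 10, nchar(s) + 20),
                   a2 = c(nchar(s) + 24, nchar(s) + 52),
                   a3 = c(nchar(s) + 56, nchar(s) + 65),
                   n_res = nchar(s) + 65)
    detect_tails(paste0(s, strrep("A", 65)), f)$net_charge[1]
  }
  withr::local_seed(23)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:10) {
    a <- paste(sample(aas, 8, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 9, replace = TRUE), collapse = "")
    expect_equal(qof(paste0(a, b)), qof(a) + qof(b) - qof(""))
    expect_equal(qof(a), qof(paste(rev(strsplit(a, "")[[1]]), collapse = "")))
  }
})

test_that("ZZ-type zinc sites are found in their interleaved arrangement", {
  # constructed from the published HMM-profile layout (C10,C13,C41,C43 C4
  # site; C26,C31,H49,H55 C2H2 site)
  s <- strsplit(strrep("A", 70), "")[[1]]
  s[c(10, 13, 41, 43)] <- "C"; s[c(26, 31)] <- "C"; s[c(49, 55)] <- "H"
  hits <- detect_zinc_motifs(paste(s, collapse = ""))
  expect_gte(length(hits), 1L)
  expect_equal(hits[[1]]$c4, c(10L, 13L, 41L, 43L))
  expect_equal(hits[[1]]$c2h2, c(26L, 31L, 49L, 55L))
  # synthetic stand-in with the published D0LYE7 positions
  s2 <- strsplit(strrep("A", 80), "")[[1]]
  s2[c(20, 23, 51, 53)] <- "C"; s2[c(36, 41)] <- "C"; s2[c(59, 65)] <- "H"
  hits2 <- detect_zinc_motifs(paste(s2, collapse = ""))
  expect_equal(hits2[[1]]$c4, c(20L, 23L, 51L, 53L))
  expect_equal(hits2[[1]]$c2h2, c(36L, 41L, 59L, 65L))
  expect_equal(length(detect_zinc_motifs(strrep("A", 70))), 0L)
})

test_that("zinc-site spatial clustering uses side-chain proxies under 8 A", {
  s <- strsplit(strrep("A", 70), "")[[1]]
  s[c(10, 13, 41, 43)] <- "C"; s[c(26, 31)] <- "C"; s[c(49, 55)] <- "H"
  seqstr <- paste(s, collapse = "")
  # clustered: all site residues within a 4 A ball, everything else far
  xyz <- cbind(seq(0, by = 20, length.out = 70), 0, 0)
  site <- c(10, 13, 41, 43, 26, 31, 49, 55)
  xyz[site, ] <- cbind(runif(8, 0, 3), runif(8, 0, 3), runif(8, 0, 3))
  m <- ca_model(xyz, resn = ifelse(seq_len(70) %in% site,
                                   ifelse(s == "H", "HIS", "CYS")[seq_len(70)], "ALA"))
  hits <- detect_zinc_motifs(seqstr, m, "A")
  expect_true(hits[[1]]$spatially_clustered)
  # spread out: not clustered
  m2 <- ca_model(cbind(seq(0, by = 20, length.out = 70), 0, 0), resn = "ALA")
  hits2 <- detect_zinc_motifs(seqstr, m2, "A")
  expect_false(hits2[[1]]$spatially_clustered)
})

test_that("P-loop scan matches the Walker A pattern", {
  expect_equal(detect_ploop("AAGASGVGKTAA"), 3L)
  expect_equal(length(detect_ploop("AAGASGVGQTAA")), 0L)
})

test_that("transmembrane segments follow windowed Kyte-Doolittle hydropathy", {
  tm <- detect_transmembrane(paste0(strrep("S", 10), strrep("L", 30), strrep("S", 10)))
  expect_equal(nrow(tm), 1L)
  expect_gte(tm$end - tm$start + 1L, 19L)
  expect_equal(nrow(detect_transmembrane(strrep("D", 40))), 0L)
  # alternating Leu/Asp: windowed mean (3.8 - 3.5)/2 = 0.15 < 1.6
  alt <- paste(rep(c("L", "D"), 20), collapse = "")
  expect_equal(nrow(detect_transmembrane(alt)), 0L)
  expect_error(detect_transmembrane("LLLL"), "shorter than")
})

test_that("hydropathy windows match a brute-force computation", {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  withr::local_seed(31)
  for (k in 1:20) {
    s <- sample(names(kd), 60, replace = TRUE)
    seg <- detect_transmembrane(paste(s, collapse = ""))
    pass <- vapply(1:(60 - 18), function(i) mean(kd[s[i:(i + 18)]]) > 1.6,
                   logical(1))
    # every residue covered by a reported segment lies in a passing window run
    covered <- rep(FALSE, 60)
    if (nrow(seg)) for (r in seq_len(nrow(seg)))
      covered[seg$start[r]:seg$end[r]] <- TRUE
    covered_oracle <- rep(FALSE, 60)
    for (i in which(pass)) covered_oracle[i:(i + 18)] <- TRUE
    expect_equal(covered, covered_oracle)
    # segments never overlap, and each interior window passes
    if (nrow(seg) > 1) expect_true(all(diff(seg$start) > 0) &&
                                     all(seg$start[-1] > seg$end[-nrow(seg)]))
    if (nrow(seg)) for (r in seq_len(nrow(seg)))
      for (i in seg$start[r]:(seg$end[r] - 18))
        expect_gt(mean(kd[s[i:(i + 18)]]), 1.6)
  }
})

test_that("conservation profile matches the closed-form pseudocount formula", {
  # column of 100x R, pseudocount 0.5: f_R = 100.5/110, others 0.5/110
  msa <- rep("R", 100)
  prof <- conservation_profile(msa <- paste0(msa, "A"))  # 2 columns, 100 rows
  f <- c(100.5 / 110, rep(0.5 / 110, 19))
  ic_expected <- log2(20) + sum(f * log2(f))
  expect_equal(prof$columns$ic[1], ic_expected, tolerance = 1e-9)
  # a perfectly uniform column has IC exactly 0
  uni <- vapply(1:100, function(i) strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]][(i - 1) %% 20 + 1],
                character(1))
  expect_equal(conservation_profile(uni)$columns$ic[1], 0, tolerance = 1e-12)
})

test_that("profile invariants hold on random alignments", {
  withr::local_seed(41)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:5) {
    rows <- vapply(1:20, function(i)
      paste(sample(c(aas, "-"), 30, replace = TRUE), collapse = ""), character(1))
    prof <- conservation_profile(rows)
    expect_true(all(abs(rowSums(prof$freq) - 1) < 1e-9))
    expect_true(all(prof$columns$ic >= 0 & prof$columns$ic <= log2(20) + 1e-12))
    # permutation invariance across rows
    prof2 <- conservation_profile(sample(rows))
    expect_equal(prof2$columns$ic, prof$columns$ic)
  }
  expect_error(conservation_profile(c("ABC", "ABCD")), "ragged")
  expect_error(conservation_profile("AAA"), "at least 2")
})

test_that("gap columns map to no reference position", {
  prof <- conservation_profile(c("A-CD", "A-C-", "A--D"))
  expect_equal(prof$columns$reference_position, c(1L, NA, 2L, 3L))
  expect_true(is.na(prof$columns$reference_position[2]))
})

test_that("FASTA and Stockholm readers round-trip sequences", {
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(seq1 = "MARVTQQQADKL", seq2 = "AAAA"), p)
  back <- read_fasta(p)
  expect_identical(unname(back), c("MARVTQQQADKL", "AAAA"))
  expect_identical(names(back), c("seq1", "seq2"))
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "", "s1 MAR-VT", "s2 MARQVT", "//"), sto)
  msa <- read_msa(sto)
  expect_identical(unname(msa), c("MAR-VT", "MARQVT"))
  # profile export is a readable TSV
  out <- withr::local_tempfile(fileext = ".tsv")
  write_profile(conservation_profile(msa), out)
  tab <- read.delim(out)
  expect_equal(nrow(tab), 6L)
  expect_true(all(c("column", "ic") %in% names(tab)))
})
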