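# brute-force O(N^2) contact oracle, independent of the package path
brute_contacts <- function(model, cutoff) {
  ca <- hf_ca(model)
  n <- 0L
  for (i in seq_len(nrow(ca) - 1L)) for (j in seq(i + 1L, nrow(ca))) {
    if (ca$chain[i] == ca$chain[j]) next
    d <- sqrt((ca$x[i] - ca$x[j])^2 + (ca$y[i] - ca$y[j])^2 + (ca$z[i] - ca$z[j])^2)
    if (d <= cutoff) n <- n + 1L
  }
  n
}

test_that("contact map equals the brute-force all-pairs count", {
  fx <- fx_dimer()
  for (cut in c(5, 8, 12)) {
    got <- nrow(find_interchain_contacts(fx$model, cut)$pairs)
    expect_equal(got, brute_contacts(fx$model, cut))
  }
  # random two-chain clouds
  withr::local_seed(3)
  for (k in 1:10) {
    xyz <- matrix(rnorm(60, 0, 6), 20, 3)
    m <- hf_structure(data.frame(chain = rep(c("A", "B"), each = 10),
                                 resi = rep(1:10, 2), resn = "GLY", atom = "CA",
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 plddt = 90))
    expect_equal(nrow(find_interchain_contacts(m, 8)$pairs), brute_contacts(m, 8))
  }
})

test_that("contact map edge cases behave", {
  fx <- fx_dimer()
  expect_equal(nrow(find_interchain_contacts(fx$model, 0)$pairs), 0L)
  far <- assemble_oligomer(arch_alpha3(), "separated_chains", seed = 1)$model
  sub <- far; sub$atoms <- sub$atoms[sub$atoms$chain %in% c("A", "B"), ]
  expect_equal(nrow(find_interchain_contacts(sub, 8)$pairs), 0L)
  expect_error(find_interchain_contacts(fx_nuc_monomer()$model), "monomer")
})

test_that("handshake dimers are detected with the built crossing angle", {
  fx <- fx_dimer()
  anns <- lapply(hf_chains(fx$model), function(c) detect_histone_fold(fx$model, c))
  names(anns) <- hf_chains(fx$model)
  hs <- detect_handshake_dimer(fx$model, anns)
  expect_true(hs$is_handshake)
  expect_gte(hs$crossing_angle, 25); expect_lte(hs$crossing_angle, 35)
  expect_gte(hs$n_a2_contacts, 10)
  # two distant chains: not a handshake
  far <- assemble_oligomer(arch_alpha3(), "separated_chains", seed = 1)$model
  far$atoms <- far$atoms[far$atoms$chain %in% c("A", "B"), ]
  fanns <- lapply(c("A", "B"), function(c) detect_histone_fold(far, c))
  names(fanns) <- c("A", "B")
  expect_false(detect_handshake_dimer(far, fanns)$is_handshake)
  expect_error(detect_handshake_dimer(fx_nuc_monomer()$model, anns), "2 chains")
  expect_error(detect_handshake_dimer(fx$model, list()), "missing fold")
})

test_that("interface confidence implements the sub-10-Angstrom PAE gate", {
  block <- function(ab, ba, intra = 2, n = 3) {
    v <- matrix(NA_real_, 2 * n, 2 * n)
    v[1:n, 1:n] <- intra; v[(n + 1):(2 * n), (n + 1):(2 * n)] <- intra
    v[1:n, (n + 1):(2 * n)] <- ab; v[(n + 1):(2 * n), 1:n] <- ba
    hf_pae(v, c(A = n, B = n))
  }
  ic <- interface_confidence(block(5, 5), "A", "B")
  expect_equal(ic$mean_interchain_pae, 5.0)
  expect_identical(ic$quality, "high")
  expect_identical(interface_confidence(block(25, 25), "A", "B")$quality, "low")
  # hand-computed mean over both blocks: (4 + 8) / 2
  ic2 <- interface_confidence(block(4, 8), "A", "B")
  expect_equal(ic2$mean_interchain_pae, 6.0)
  expect_identical(ic2$quality, "high")
  # boundary: mean exactly 10 is LOW quality
  expect_identical(interface_confidence(block(10, 10), "A", "B")$quality, "low")
  expect_error(interface_confidence(block(5, 5), "A", "Z"), "not in PAE")
})

test_that("interface quality is monotone non-increasing in every PAE entry", {
  withr::local_seed(5)
  for (k in 1:20) {
    v <- matrix(runif(36, 0, 20), 6, 6)
    pae <- hf_pae(v, c(A = 3L, B = 3L))
    q1 <- interface_confidence(pae, "A", "B")
    bumped <- v; i <- sample(6, 1); j <- sample(6, 1)
    bumped[i, j] <- bumped[i, j] + runif(1, 0, 15)
    q2 <- interface_confidence(hf_pae(bumped, c(A = 3L, B = 3L)), "A", "B")
    expect_gte(q2$mean_interchain_pae, q1$mean_interchain_pae)
    if (q1$quality == "low") expect_identical(q2$quality, "low")
  }
})

tet_anns <- function(model) {
  ch <- hf_chains(model)
  anns <- lapply(ch, function(c) detect_histone_fold(model, c))
  names(anns) <- ch
  anns
}

test_that("tetramer topologies are classified from their fold elements", {
  ftf <- fx_ftf()
  tc <- classify_tetramer_topology(ftf$model, tet_anns(ftf$model))
  expect_identical(tc$topology, "ftf_torus")
  expect_equal(sum(tc$interfaces$n >= 3), 2L)  # exactly two inter-dimer interfaces

  open <- assemble_oligomer(arch_nucleosomal(), "open_stack_tetramer", seed = 2)
  expect_identical(classify_tetramer_topology(open$model, tet_anns(open$model))$topology,
                   "open_stack")

  cc <- assemble_oligomer(arch_nucleosomal(c_flank = list(length = 25L, kind = "cc_extension")),
                          "cc_tetramer", seed = 2)
  expect_identical(classify_tetramer_topology(cc$model, tet_anns(cc$model))$topology,
                   "cc_bundle")

  ct <- assemble_oligomer(arch_alpha3(c_flank = list(length = 20L, kind = "cc_extension")),
                          "ctail_tetramer", seed = 2)
  expect_identical(classify_tetramer_topology(ct$model, tet_anns(ct$model))$topology,
                   "ctail_tetramer")

  far <- assemble_oligomer(arch_alpha3(), "separated_chains", seed = 2)
  expect_identical(classify_tetramer_topology(far$model, tet_anns(far$model))$topology,
                   "none")
})

test_that("tetramer topology is invariant under relabeling and rigid moves", {
  ftf <- fx_ftf()
  m <- ftf$model
  withr::local_seed(9)
  moved <- hf_transform(m, random_rotation(), rnorm(3, 0, 25))
  expect_identical(classify_tetramer_topology(moved, tet_anns(moved))$topology,
                   "ftf_torus")
  # relabel chains A,B,C,D -> D,C,B,A (atom order preserved per chain)
  relab <- m
  map <- c(A = "D", B = "C", C = "B", D = "A")
  relab$atoms$chain <- unname(map[relab$atoms$chain])
  expect_identical(classify_tetramer_topology(relab, tet_anns(relab))$topology,
                   "ftf_torus")
})

test_that("fused flanking domains are flagged by size and compactness", {
  zz <- build_fold_monomer(arch_alpha3(n_flank = list(length = 60L, kind = "compact_domain")),
                           seed = 1)
  ann <- detect_histone_fold(zz$model, "A")
  dom <- detect_extra_domains(zz$model, ann)
  expect_equal(nrow(dom), 1L)
  expect_identical(dom$side, "N")
  expect_gte(dom$length, 60L)
  expect_true(dom$compact)
  # bare fold: nothing
  bare <- fx_nuc_monomer()
  expect_equal(nrow(detect_extra_domains(bare$model,
                                         detect_histone_fold(bare$model, "A"))), 0L)
  # a 20-residue extension is below the domain threshold
  tail20 <- build_fold_monomer(arch_nucleosomal(c_flank = list(length = 20L, kind = "charged_tail")),
                               seed = 1)
  expect_equal(nrow(detect_extra_domains(tail20$model,
                                         detect_histone_fold(tail20$model, "A"))), 0L)
})

test_that("wrapped-diameter model adds two DNA diameters to the in-plane extent", {
  # flat disk with known in-plane extent 43 A (plus tiny thickness)
  withr::local_seed(2)
  ang <- runif(200, 0, 2 * pi)
  xyz <- cbind(21.5 * cos(ang), 21.5 * sin(ang), runif(200, -1, 1))
  m <- hf_structure(data.frame(chain = rep(c("A", "B", "C", "D"), each = 50),
                               resi = rep(1:50, 4), resn = "GLY", atom = "CA",
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], plddt = 90))
  expect_equal(estimate_wrapped_diameter(m), 8.3, tolerance = 0.01)
  # degenerate single-point cloud: 2 x dna_diameter only
  pt <- hf_structure(data.frame(chain = c("A", "B", "C", "D"), resi = 1,
                                resn = "GLY", atom = "CA", x = 0, y = 0, z = 0,
                                plddt = 90))
  expect_equal(estimate_wrapped_diameter(pt), 4.0)
  # exact additivity in dna_diameter
  ftf <- fx_ftf()
  expect_equal(estimate_wrapped_diameter(ftf$model, 0) + 4.0,
               estimate_wrapped_diameter(ftf$model, 2.0))
  expect_error(estimate_wrapped_diameter(fx_dimer()$model), "tetramer")
})

test_that("assign_category follows the decision tree with PAE gating", {
  hs_hi <- list(is_handshake = TRUE, confidence = "high", dimerizing_ctail = FALSE)
  hs_lo <- list(is_handshake = TRUE, confidence = "low", dimerizing_ctail = FALSE)
  tc <- function(topo, conf = "high")
    structure(list(topology = topo, confidence = conf, interfaces = NULL,
                   reason = ""), class = "hf_topology")
  expect_identical(assign_category("alpha3", hs_hi, tc("ftf_torus"))$category, "ftf")
  # low-confidence torus is skipped: falls back to the dimer-level call
  expect_identical(assign_category("alpha3", hs_hi, tc("ftf_torus", "low"))$category,
                   "bacterial_dimer")
  # everything low-confidence: undefined
  expect_identical(assign_category("alpha3", hs_lo, tc("ftf_torus", "low"))$category,
                   "undefined")
  expect_identical(assign_category("alpha3", hs_hi, tc("ctail_tetramer"))$category,
                   "phage_like")
  expect_identical(assign_category("nucleosomal", hs_hi, tc("ctail_tetramer"))$category,
                   "mc_like")
  cc <- assign_category("nucleosomal", hs_hi, tc("cc_bundle"),
                        seqfeat = list(cterm_helix_len = 34))
  expect_identical(cc$category, "coiled_coil"); expect_true(cc$rdgc_flag)
  cc2 <- assign_category("nucleosomal", hs_hi, tc("cc_bundle"),
                         seqfeat = list(cterm_helix_len = 25))
  expect_false(cc2$rdgc_flag)
  ihf <- list(is_handshake = TRUE, confidence = "high", dimerizing_ctail = TRUE)
  expect_identical(assign_category("nucleosomal", ihf)$category, "ihf_like")
  expect_identical(assign_category("nucleosomal", hs_hi, tc("open_stack"))$category,
                   "nucleosomal")
  # transmembrane beats everything when the alpha1 face lost its basics
  expect_identical(assign_category("nucleosomal",
                                   seqfeat = list(n_basic_alpha1 = 0L, has_tm = TRUE))$category,
                   "transmembrane")
  dom <- data.frame(side = "N", start = 1, end = 64, length = 64, rg = 9,
                    compact = TRUE)
  expect_identical(assign_category("alpha3", domains = dom,
                                   seqfeat = list(has_zz = TRUE))$category, "zz")
  dom130 <- transform(dom, length = 134, end = 134)
  expect_identical(assign_category("alpha3", domains = dom130,
                                   seqfeat = list(has_ploop = TRUE))$category,
                   "rab_gtpase")
  expect_identical(assign_category(NA_character_)$category, "undefined")
})
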