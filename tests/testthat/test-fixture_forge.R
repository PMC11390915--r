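test_that("the generator is deterministic per seed", {
  a <- build_fold_monomer(arch_nucleosomal(), seed = 7, jitter_sigma = 0.2)
  b <- build_fold_monomer(arch_nucleosomal(), seed = 7, jitter_sigma = 0.2)
  expect_identical(a$model$atoms, b$model$atoms)
  c <- build_fold_monomer(arch_nucleosomal(), seed = 8, jitter_sigma = 0.2)
  expect_false(identical(a$model$atoms, c$model$atoms))
  s1 <- synth_sequence_set(arch_alpha3(), seed = 5)
  s2 <- synth_sequence_set(arch_alpha3(), seed = 5)
  expect_identical(s1$sequence, s2$sequence)
  # generator calls do not disturb the caller's RNG stream
  set.seed(99); r1 <- runif(1)
  set.seed(99); invisible(build_fold_monomer(arch_alpha3(), seed = 3,
                                             jitter_sigma = 0.1))
  expect_identical(runif(1), r1)
})

test_that("architecture presets carry the defining helix lengths", {
  n <- arch_nucleosomal()
  expect_equal(c(n$alpha1, n$alpha2, n$alpha3, n$l1, n$l2), c(11, 29, 10, 3, 3))
  a <- arch_alpha3()
  expect_equal(c(a$alpha1, a$alpha2, a$alpha3, a$l1, a$l2), c(11, 25, 4, 3, 3))
  expect_equal(arch_length(n), 56L)
  expect_error(fold_architecture(alpha1 = 0), ">= 1")
  expect_error(fold_architecture(n_flank = list(length = 5, kind = "bogus")),
               "unknown flank kind")
  expect_error(assemble_oligomer(arch_nucleosomal(), "cc_tetramer"),
               "cc_extension")
})

test_that("every assembly is recovered by its classifier (self-consistency)", {
  # monomers
  expect_identical(as.character(detect_histone_fold(
    fx_nuc_monomer()$model, "A")$fold_family), "nucleosomal")
  expect_identical(as.character(detect_histone_fold(
    fx_a3_monomer()$model, "A")$fold_family), "alpha3")
  # dimer and torus are covered in test-quaternary; here the chain count
  # and ground-truth span bookkeeping
  fx <- fx_ftf()
  expect_equal(length(hf_chains(fx$model)), 4L)
  expect_identical(fx$truth$topology, "ftf_tetramer")
  tr <- fx$truth$chains$A
  ann <- detect_histone_fold(fx$model, "A")
  expect_lte(abs(ann$fold_span[["start"]] - tr$fold_span[1]), 2)
  expect_lte(abs(ann$fold_span[["end"]] - tr$fold_span[2]), 2)
})

test_that("synth_confidence writes pLDDT tracks and block PAE matrices", {
  arch <- arch_nucleosomal(c_flank = list(length = 20L, kind = "charged_tail"))
  fx <- assemble_oligomer(arch, "handshake_dimer", seed = 3)
  conf <- synth_confidence(fx$model, fx$truth, core_plddt = 88, tail_plddt = 31,
                           intra_pae = 3, inter_pae = 5)
  ca <- hf_ca(conf$model, "A")
  span <- fx$truth$chains$A$fold_span
  expect_true(all(ca$plddt[span[1]:span[2]] == 88))
  expect_true(all(ca$plddt[(span[2] + 1):nrow(ca)] == 31))
  n <- nrow(conf$pae$values)
  expect_equal(n, sum(vapply(hf_chains(fx$model),
                             function(c) nrow(hf_ca(fx$model, c)), integer(1))))
  expect_identical(interface_confidence(conf$pae, "A", "B")$quality, "high")
  low <- synth_confidence(fx$model, fx$truth, inter_pae = 25)
  expect_identical(interface_confidence(low$pae, "A", "B")$quality, "low")
  expect_error(synth_confidence(fx$model, fx$truth, core_plddt = 150))
})

test_that("synthetic sequences carry exactly the implanted features", {
  for (seed in 1:5) {
    arch <- arch_alpha3(n_flank = list(length = 60L, kind = "compact_domain"))
    sq <- synth_sequence_set(arch, list(zz_sites = TRUE), seed = seed)
    expect_equal(nchar(sq$sequence), arch_length(arch))
    hits <- scan_l2_motif(sq$sequence)
    expect_equal(hits$anchor_position, sq$truth$motif_anchor)
    zz <- detect_zinc_motifs(sq$sequence)
    expect_true(any(vapply(zz, function(h)
      identical(h$c4, sq$truth$zz$c4), logical(1))))
    expect_equal(nrow(detect_transmembrane(sq$sequence)), 0L)
    expect_equal(length(detect_ploop(sq$sequence)), 0L)
    # feature-free sequences scan clean everywhere
    plain <- synth_sequence_set(arch_nucleosomal(),
                                list(motif = FALSE, basic_alpha1 = FALSE),
                                seed = seed)
    expect_equal(nrow(scan_l2_motif(plain$sequence)), 0L)
    expect_equal(length(detect_zinc_motifs(plain$sequence)), 0L)
    expect_equal(nrow(detect_transmembrane(plain$sequence)), 0L)
  }
})

test_that("synthetic MSAs have conserved and free columns as specified", {
  aln <- synth_msa(list("R", NA, "K"), n_sequences = 100, seed = 9)
  expect_equal(length(aln), 100L)
  expect_true(all(nchar(aln) == 3L))
  prof <- conservation_profile(aln)
  # closed-form expectation for a 0.95-conserved column of n = 100 with
  # 0.5 pseudocounts: f_cons = 95.5/110, f_other = (5/19 + 0.5)/110
  f <- c(95.5 / 110, rep((5 / 19 + 0.5) / 110, 19))
  ic_expected <- log2(20) + sum(f * log2(f))
  expect_gte(prof$columns$ic[1], ic_expected - 0.6)
  expect_lte(prof$columns$ic[1], log2(20))
  expect_lt(prof$columns$ic[2], 0.5)
  expect_gte(prof$columns$ic[3], ic_expected - 0.6)
  expect_error(synth_msa(list("R"), 1), "at least 2")
})

test_that("golden suite artifacts are byte-identical across reruns", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_golden_suite(d1, seed = 11)
  write_golden_suite(d2, seed = 11)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
})

test_that("0.3 A jitter never changes a golden-suite classification", {
  d <- withr::local_tempdir()
  gs <- write_golden_suite(d, seed = 42, jitter_sigma = 0.3)
  report <- run_batch(gs$manifest, log_fun = NULL)
  cmp <- merge(report, gs$truth, by = "protein_id")
  expect_identical(cmp$category, cmp$expected_category)
  expect_identical(cmp$rdgc_flag, cmp$expected_rdgc)
})
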