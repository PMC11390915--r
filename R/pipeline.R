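# Batch classification pipeline: one report row per prediction record,
# reproducing the manual monomer -> multimer -> PAE -> category workflow as
# auditable code. Per-record failures never stop the batch.

#' Default pipeline configuration
#'
#' Every numeric threshold of the pipeline in one list, overridable from a
#' JSON config file (see [read_config()]). The report records an MD5 hash
#' of the configuration actually used.
#'
#' @return named list of thresholds
#' @export
hf_config <- function() {
  list(
    contact_cutoff = 8.0,        # CA-CA contact distance, Angstrom
    pae_threshold = 10.0,        # interface mean PAE below this = high quality
    min_a2_contacts = 10L,       # handshake: alpha2-alpha2 contact floor
    crossing_angle_min = 15, crossing_angle_max = 60,  # handshake, degrees
    min_interface_contacts = 3L, # contacts for a chain pair to count as interface
    dominance = 0.6,             # element-dominance fraction for topologies
    alpha3_max = 5L,             # fold family: alpha3 when a3 length <= this
    nucleosomal_min = 8L,        # fold family: nucleosomal when a3 >= this
    tail_min_len = 5L,           # minimum flank length reported as tail
    disorder_plddt = 50,         # tails below this mean pLDDT are disordered
    domain_min_len = 25L,        # minimum flank length for a fused domain
    rab_domain_min_len = 120L,   # Rab GTPase domain minimum size
    tm_window = 19L, tm_threshold = 1.6,   # Kyte-Doolittle
    rdgc_helix_min = 30L         # C-helix length flagging rdgc-like
  )
}

#' Read a JSON configuration file, filling unset values with defaults
#' @param path JSON file with a subset of [hf_config()] fields
#' @return full configuration list
#' @export
read_config <- function(path = NULL) {
  cfg <- hf_config()
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) stop("unknown config fields: ",
                              paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# pick the 4-chain sub-assembly with the most inter-chain contacts
reduce_to_tetramer <- function(model, cutoff = 8.0) {
  chains <- hf_chains(model)
  if (length(chains) <= 4L) return(model)
  combs <- utils::combn(chains, 4L, simplify = FALSE)
  score <- vapply(combs, function(cs) {
    sub <- model; sub$atoms <- sub$atoms[sub$atoms$chain %in% cs, ]
    sum(find_interchain_contacts(sub, cutoff)$counts$n)
  }, numeric(1))
  best <- combs[[which.max(score)]]
  model$atoms <- model$atoms[model$atoms$chain %in% best, ]
  model
}

#' Classify one prediction record
#'
#' Runs fold detection on the monomer, handshake/topology classification on
#' the multimers with PAE confidence gating, sequence-feature annotation,
#' and finally [assign_category()]; every decision is appended to the
#' evidence trail. Missing multimer or PAE files downgrade the affected
#' rules and are recorded as warnings instead of failing the record.
#'
#' @param rec list or one-row data.frame with fields `protein_id`,
#'   `monomer` (required path) and optional paths `dimer`, `tetramer`,
#'   `hexamer`, `dimer_pae`, `tetramer_pae`, `hexamer_pae`, `fasta`
#' @param config configuration list from [hf_config()]/[read_config()]
#' @return one-row data.frame (a report row)
#' @export
classify_record <- function(rec, config = hf_config()) {
  # all predictions are homomers: when per-chain fold detection fails on a
  # multimer chain (noise), the monomer annotation is reused if the chain
  # has the same residue count
  ann_chain <- function(model, ch, fallback) {
    a <- detect_histone_fold(model, ch)
    if (is.null(a) && !is.null(fallback) &&
        nrow(hf_ca(model, ch)) == fallback$n_res) {
      a <- fallback
      a$chain <- ch
    }
    a
  }
  rec <- as.list(rec)
  warnings <- character(); evidence <- character()
  warn <- function(...) warnings <<- c(warnings, sprintf(...))
  note <- function(...) evidence <<- c(evidence, sprintf(...))
  has <- function(f) !is.null(rec[[f]]) && !is.na(rec[[f]]) && nzchar(rec[[f]])
  row <- function(category, confidence, fold = NULL, handshake = NULL,
                  tet = NULL, pae_txt = NA_character_, rdgc = FALSE) {
    data.frame(
      protein_id = rec$protein_id,
      fold_family = if (is.null(fold)) NA_character_ else as.character(fold$fold_family),
      alpha1_len = if (is.null(fold)) NA_integer_ else fold$alpha1[["length"]],
      alpha2_len = if (is.null(fold)) NA_integer_ else fold$alpha2[["length"]],
      alpha3_len = if (is.null(fold)) NA_integer_ else fold$alpha3[["length"]],
      dimer_handshake = if (is.null(handshake)) NA else handshake$is_handshake,
      crossing_angle = if (is.null(handshake)) NA_real_ else round(handshake$crossing_angle, 1),
      tetramer_topology = if (is.null(tet)) NA_character_ else tet$topology,
      interface_pae = pae_txt,
      category = category,
      rdgc_flag = rdgc,
      confidence = confidence,
      evidence = paste(evidence, collapse = "; "),
      warnings = paste(warnings, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  if (!has("monomer")) {
    warn("no monomer structure given")
    return(row("undefined", "low"))
  }
  monomer <- tryCatch(read_structure(rec$monomer), error = function(e) {
    warn("monomer unreadable: %s", conditionMessage(e)); NULL
  })
  if (is.null(monomer)) return(row("undefined", "low"))
  ch1 <- hf_chains(monomer)[1]
  fold <- detect_histone_fold(monomer, ch1)
  if (is.null(fold)) {
    warn("no histone fold detected in the monomer")
    return(row("undefined", "low"))
  }
  fold$fold_family <- classify_fold_family(fold)
  note("fold %s (a1/a2/a3 = %d/%d/%d)", fold$fold_family,
       fold$alpha1[["length"]], fold$alpha2[["length"]], fold$alpha3[["length"]])

  # sequence features
  seqstr <- NULL
  if (has("fasta")) {
    seqstr <- tryCatch(read_fasta(rec$fasta)[[1]], error = function(e) {
      warn("fasta unreadable: %s", conditionMessage(e)); NULL
    })
    if (!is.null(seqstr) && nchar(seqstr) != fold$n_res) {
      warn("fasta length %d != monomer length %d; using monomer-derived sequence",
           nchar(seqstr), fold$n_res)
      seqstr <- NULL
    }
  }
  if (is.null(seqstr)) seqstr <- hf_sequence(monomer, ch1)
  domains <- detect_extra_domains(monomer, fold)
  basic <- find_basic_alpha1_residues(seqstr, fold, monomer, ch1)
  tm <- detect_transmembrane(seqstr, config$tm_window, config$tm_threshold)
  zz <- detect_zinc_motifs(seqstr)
  ploop <- detect_ploop(seqstr)
  motifs <- scan_l2_motif(seqstr, fold)
  if (nrow(motifs)) note("L2 motif %s at %d", motifs$pattern_name[1],
                         motifs$anchor_position[1])
  sse1 <- assign_secondary_structure(monomer, ch1)
  post <- fold_positions(fold, "post_fold")
  cterm_helix <- if (length(post)) {
    runs <- sse_runs(paste(strsplit(sse1, "")[[1]][post], collapse = ""))
    if (nrow(runs)) max(runs$length) else 0L
  } else 0L
  seqfeat <- list(has_zz = length(zz) > 0, has_ploop = length(ploop) > 0,
                  has_tm = nrow(tm) > 0, n_basic_alpha1 = length(basic),
                  cterm_helix_len = cterm_helix)

  # dimer
  handshake <- NULL
  pae_notes <- character()
  if (has("dimer")) {
    handshake <- tryCatch({
      dim_model <- read_structure(rec$dimer)
      dch <- hf_chains(dim_model)
      anns <- lapply(dch, function(c) ann_chain(dim_model, c, fold))
      names(anns) <- dch
      contacts <- find_interchain_contacts(dim_model, config$contact_cutoff)
      hs <- detect_handshake_dimer(dim_model, anns, contacts)
      hs$confidence <- NA_character_
      if (has("dimer_pae")) {
        lens <- vapply(dch, function(c) nrow(hf_ca(dim_model, c)), integer(1))
        pae <- read_pae(rec$dimer_pae, stats::setNames(lens, dch))
        ic <- interface_confidence(pae, dch[1], dch[2])
        hs$confidence <- ic$quality
        pae_notes <- c(pae_notes, sprintf("dimer %.1f (%s)",
                                          ic$mean_interchain_pae, ic$quality))
      } else warn("dimer PAE missing: handshake evidence not usable for categorization")
      hs$dimerizing_ctail <- !any(vapply(anns, is.null, logical(1))) &&
        detect_dimerizing_ctail(dim_model, anns, contacts)
      hs
    }, error = function(e) { warn("dimer skipped: %s", conditionMessage(e)); NULL })
    if (!is.null(handshake))
      note("dimer: handshake=%s angle=%.0f deg (%d a2 contacts)",
           handshake$is_handshake, handshake$crossing_angle, handshake$n_a2_contacts)
  }

  # tetramer (a hexamer is reduced to its best 4-chain sub-assembly)
  tet <- NULL
  tet_src <- if (has("tetramer")) "tetramer" else if (has("hexamer")) "hexamer" else NULL
  if (!is.null(tet_src)) {
    tet <- tryCatch({
      tmod <- read_structure(rec[[tet_src]])
      full_ch <- hf_chains(tmod)
      if (length(full_ch) > 4L) {
        tmod <- reduce_to_tetramer(tmod, config$contact_cutoff)
        warn("%d-chain %s reduced to best tetramer sub-assembly",
             length(full_ch), tet_src)
      }
      tch <- hf_chains(tmod)
      anns <- lapply(tch, function(c) ann_chain(tmod, c, fold))
      names(anns) <- tch
      pae <- NULL
      pae_field <- paste0(tet_src, "_pae")
      if (has(pae_field)) {
        lens <- vapply(tch, function(c) nrow(hf_ca(tmod, c)), integer(1))
        pae <- tryCatch(read_pae(rec[[pae_field]], stats::setNames(lens, tch)),
                        error = function(e) {
                          warn("%s unreadable: %s", pae_field, conditionMessage(e)); NULL
                        })
      } else warn("%s PAE missing: tetramer rules skipped", tet_src)
      tc <- classify_tetramer_topology(
        tmod, anns, find_interchain_contacts(tmod, config$contact_cutoff), pae,
        min_interface_contacts = config$min_interface_contacts,
        dominance = config$dominance)
      if (!is.null(pae) && !is.null(tc$interfaces)) {
        act <- tc$interfaces[tc$interfaces$n >= config$min_interface_contacts, ]
        if (nrow(act)) {
          ms <- vapply(seq_len(nrow(act)), function(k)
            interface_confidence(pae, act$chain_a[k], act$chain_b[k])$mean_interchain_pae,
            numeric(1))
          pae_notes <- c(pae_notes, sprintf("tetramer %.1f (%s)", mean(ms),
                                            tc$confidence))
        }
      }
      tc
    }, error = function(e) { warn("tetramer skipped: %s", conditionMessage(e)); NULL })
    if (!is.null(tet))
      note("tetramer topology: %s (confidence %s)", tet$topology, tet$confidence)
  } else {
    note("no multimer evidence beyond dimer")
  }

  cat_call <- assign_category(fold$fold_family, dimer = handshake,
                              tetramer = tet, domains = domains,
                              seqfeat = seqfeat)
  evidence <- c(evidence, cat_call$evidence)
  row(cat_call$category, cat_call$confidence, fold = fold,
      handshake = handshake, tet = tet,
      pae_txt = if (length(pae_notes)) paste(pae_notes, collapse = "; ") else NA_character_,
      rdgc = cat_call$rdgc_flag)
}

#' Run the classification pipeline over a manifest
#'
#' The manifest is a TSV with one row per protein and columns
#' `protein_id`, `monomer`, and optionally `dimer`, `tetramer`, `hexamer`,
#' `dimer_pae`, `tetramer_pae`, `hexamer_pae`, `fasta` (relative paths are
#' resolved against the manifest's directory). Row order is preserved;
#' per-record failures produce an `undefined` row with warnings and never
#' abort the batch.
#'
#' @param manifest path to the manifest TSV
#' @param out optional output TSV path for the report
#' @param config configuration list
#' @param log_fun function receiving one structured log line per record
#'   (default `message`); pass `NULL` to silence
#' @return the report data.frame, invisibly when `out` is given; attribute
#'   `category_counts` carries the per-category tally
#' @export
run_batch <- function(manifest, out = NULL, config = hf_config(),
                      log_fun = message) {
  if (!file.exists(manifest)) stop("manifest not readable: ", manifest)
  man <- utils::read.delim(manifest, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!"protein_id" %in% names(man))
    stop("manifest lacks a protein_id column")
  base <- dirname(normalizePath(manifest))
  pathcols <- intersect(c("monomer", "dimer", "tetramer", "hexamer",
                          "dimer_pae", "tetramer_pae", "hexamer_pae", "fasta"),
                        names(man))
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rec <- as.list(man[i, , drop = FALSE])
    for (pc in pathcols) {
      p <- rec[[pc]]
      if (!is.null(p) && !is.na(p) && nzchar(p) && !grepl("^/", p))
        rec[[pc]] <- file.path(base, p)
    }
    r <- tryCatch(classify_record(rec, config), error = function(e) {
      data.frame(protein_id = rec$protein_id, fold_family = NA_character_,
                 alpha1_len = NA_integer_, alpha2_len = NA_integer_,
                 alpha3_len = NA_integer_, dimer_handshake = NA,
                 crossing_angle = NA_real_, tetramer_topology = NA_character_,
                 interface_pae = NA_character_, category = "undefined",
                 rdgc_flag = FALSE, confidence = "low", evidence = "",
                 warnings = paste("record failed:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    if (!is.null(log_fun))
      log_fun(sprintf("[histofold] %s\tcategory=%s\tconfidence=%s",
                      r$protein_id, r$category, r$confidence))
    rows[[i]] <- r
  }
  report <- if (nrow(man)) do.call(rbind, rows) else
    classify_record(list(protein_id = "x", monomer = ""))[0, ]
  counts <- if (nrow(report)) table(report$category) else table(character())
  attr(report, "category_counts") <- counts
  if (!is.null(log_fun)) {
    log_fun(sprintf("[histofold] config=%s  %d record(s): %s",
                    config_hash(config), nrow(report),
                    paste(names(counts), as.integer(counts), sep = "=",
                          collapse = ", ")))
  }
  if (!is.null(out)) {
    utils::write.table(report, out, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(report))
  }
  report
}

# ---- golden fixture suite --------------------------------------------------

golden_fixture_specs <- function() {
  list(
    list(id = "nuc_monomer", preset = "nucleosomal", topo = NULL,
         expected = "nucleosomal"),
    list(id = "nuc_dimer", preset = "nucleosomal", topo = "handshake_dimer",
         expected = "nucleosomal"),
    list(id = "nuc_open_stack", preset = "nucleosomal",
         topo = "open_stack_tetramer", expected = "nucleosomal"),
    list(id = "a3_dimer", preset = "alpha3", topo = "handshake_dimer",
         expected = "bacterial_dimer"),
    list(id = "a3_ftf", preset = "alpha3", topo = "ftf_tetramer",
         expected = "ftf"),
    list(id = "a3_ftf_lowpae", preset = "alpha3", topo = "ftf_tetramer",
         inter_pae = 25, expected = "bacterial_dimer"),
    list(id = "a3_separated", preset = "alpha3", topo = "separated_chains",
         expected = "bacterial_dimer"),
    list(id = "cc_bundle", preset = "nucleosomal", topo = "cc_tetramer",
         c_flank = list(length = 25L, kind = "cc_extension"),
         expected = "coiled_coil"),
    list(id = "rdgc_long_helix", preset = "nucleosomal", topo = "cc_tetramer",
         c_flank = list(length = 34L, kind = "cc_extension"),
         expected = "coiled_coil", rdgc = TRUE),
    list(id = "mc_ctail", preset = "nucleosomal", topo = "ctail_tetramer",
         c_flank = list(length = 20L, kind = "cc_extension"),
         expected = "mc_like"),
    list(id = "phage_ctail", preset = "alpha3", topo = "ctail_tetramer",
         c_flank = list(length = 20L, kind = "cc_extension"),
         expected = "phage_like"),
    list(id = "zz_fused", preset = "alpha3", topo = NULL,
         n_flank = list(length = 60L, kind = "compact_domain"),
         features = list(zz_sites = TRUE), expected = "zz"),
    list(id = "rab_fused", preset = "alpha3", topo = NULL,
         n_flank = list(length = 130L, kind = "compact_domain"),
         features = list(ploop = TRUE), expected = "rab_gtpase"),
    list(id = "ihf_ctail_dimer", preset = "nucleosomal", topo = "ihf_dimer",
         c_flank = list(length = 20L, kind = "ihf_tail"),
         expected = "ihf_like"),
    list(id = "tm_histone", preset = "nucleosomal", topo = NULL,
         c_flank = list(length = 25L, kind = "tm_segment"),
         features = list(basic_alpha1 = FALSE, tm = TRUE),
         expected = "transmembrane")
  )
}

fixture_arch <- function(sp) {
  preset_fun <- if (sp$preset == "alpha3") arch_alpha3 else arch_nucleosomal
  args <- list()
  if (!is.null(sp$n_flank)) args$n_flank <- sp$n_flank
  if (!is.null(sp$c_flank)) args$c_flank <- sp$c_flank
  do.call(preset_fun, args)
}

#' Write the golden fixture suite to a directory
#'
#' One subdirectory per fixture with monomer (and, where the topology asks
#' for it, dimer/tetramer) PDB files, block PAE JSONs, a FASTA sequence,
#' plus a `manifest.tsv` and a `truth.tsv` with the intended categories.
#' All topologies of the classifier are covered with both fold presets;
#' outputs are byte-identical for identical seeds.
#'
#' @param dir output directory (created if needed)
#' @param seed integer master seed; each fixture derives its own seed
#' @param jitter_sigma coordinate noise (Angstrom; default 0)
#' @param inter_pae default inter-chain PAE (Angstrom) where the fixture
#'   definition does not override it
#' @return list: `manifest` (path), `truth` (data.frame id/expected paths)
#' @export
write_golden_suite <- function(dir, seed = 42L, jitter_sigma = 0,
                               inter_pae = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- golden_fixture_specs()
  man <- NULL; truth <- NULL
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    fseed <- seed + k
    arch <- fixture_arch(sp)
    feat <- if (is.null(sp$features)) list() else sp$features
    sq <- synth_sequence_set(arch, feat, seed = fseed)
    fdir <- file.path(dir, sp$id)
    dir.create(fdir, showWarnings = FALSE)
    paths <- list(protein_id = sp$id, monomer = NA, dimer = NA, tetramer = NA,
                  hexamer = NA, dimer_pae = NA, tetramer_pae = NA,
                  hexamer_pae = NA, fasta = NA)
    # a fixture-specific inter_pae (the PAE gate fixture) applies to the
    # tetramer only; the dimer level keeps the default confident interface
    ip_tet <- if (is.null(sp$inter_pae)) inter_pae else sp$inter_pae
    emit <- function(topology, tag, arity_pae = TRUE) {
      ip <- if (tag == "tetramer") ip_tet else inter_pae
      fx <- assemble_oligomer(arch, topology, seed = fseed,
                              jitter_sigma = jitter_sigma,
                              sequence = sq$sequence)
      conf <- synth_confidence(fx$model, fx$truth, inter_pae = ip)
      pdb <- file.path(fdir, paste0(tag, ".pdb"))
      write_structure(conf$model, pdb)
      paths[[tag]] <<- file.path(sp$id, paste0(tag, ".pdb"))
      if (arity_pae && length(hf_chains(fx$model)) > 1L) {
        pj <- file.path(fdir, paste0(tag, "_pae.json"))
        write_pae(conf$pae, pj)
        paths[[paste0(tag, "_pae")]] <<- file.path(sp$id, paste0(tag, "_pae.json"))
      }
    }
    emit("monomer", "monomer")
    if (!is.null(sp$topo)) {
      if (sp$topo %in% c("handshake_dimer", "ihf_dimer")) {
        emit(sp$topo, "dimer")
      } else {
        # tetramer topologies also ship the plain dimer level
        dimer_topo <- if (sp$topo == "ihf_dimer") "ihf_dimer" else "handshake_dimer"
        if (arch$c_flank$kind != "ihf_tail") emit(dimer_topo, "dimer")
        emit(sp$topo, "tetramer")
      }
    }
    fa <- file.path(fdir, "sequence.fasta")
    write_fasta(stats::setNames(sq$sequence, sp$id), fa)
    paths$fasta <- file.path(sp$id, "sequence.fasta")
    man <- rbind(man, as.data.frame(paths, stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      protein_id = sp$id, expected_category = sp$expected,
      expected_rdgc = isTRUE(sp$rdgc), preset = sp$preset,
      topology = if (is.null(sp$topo)) "monomer" else sp$topo,
      seed = fseed, stringsAsFactors = FALSE))
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(manifest = manifest, truth = truth)
}
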