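# Shared fixtures, built lazily and cached for the whole test run.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) assign(name, builder(), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

fx_nuc_monomer <- function() fixture("nuc_monomer", function()
  build_fold_monomer(arch_nucleosomal(), seed = 42))
fx_a3_monomer <- function() fixture("a3_monomer", function()
  build_fold_monomer(arch_alpha3(), seed = 42))
fx_dimer <- function() fixture("dimer", function()
  assemble_oligomer(arch_alpha3(), "handshake_dimer", seed = 42))
fx_ftf <- function() fixture("ftf", function()
  assemble_oligomer(arch_alpha3(), "ftf_tetramer", seed = 42))
fx_golden <- function() fixture("golden", function() {
  dir <- file.path(tempdir(), "histofold-golden")
  gs <- write_golden_suite(dir, seed = 42)
  gs$dir <- dir
  gs
})

# hand-rolled fold annotation for unit tests that do not need a structure
make_fold <- function(a1 = c(1, 11), a2 = c(15, 43), a3 = c(47, 56),
                      n_res = 60, chain = "A") {
  seg <- function(p) c(start = p[1], end = p[2], length = p[2] - p[1] + 1)
  ann <- structure(list(
    chain = chain, alpha1 = seg(a1), alpha2 = seg(a2), alpha3 = seg(a3),
    l1_length = a2[1] - a1[2] - 1, l2_length = a3[1] - a2[2] - 1,
    fold_span = c(start = a1[1], end = a3[2]), n_res = n_res,
    fold_family = NA_character_), class = "hf_fold")
  ann$fold_family <- classify_fold_family(ann)
  ann
}

# structure from a bare CA coordinate matrix
ca_model <- function(xyz, chain = "A", plddt = 90, resn = "ALA") {
  hf_structure(data.frame(chain = chain, resi = seq_len(nrow(xyz)),
                          resn = resn, atom = "CA",
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          plddt = plddt))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
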