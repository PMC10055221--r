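# shared fixtures, built in code

# probability vector with mass p on one amino acid, remainder uniform
spike_vec <- function(aa, p = 0.9) {
  v <- rep((1 - p) / 19, 20)
  v[match(aa, aa_alphabet())] <- p
  v
}

uniform_vec <- function() rep(0.05, 20)

# small handmade prediction set: one protein, chosen tops per model
toy_pset <- function(tops, protein_id = "p1", p = 0.9) {
  rows <- do.call(rbind, lapply(names(tops), function(m)
    do.call(rbind, lapply(tops[[m]], spike_vec, p = p))))
  n <- length(tops[[1]])
  prediction_set(protein_id = rep(protein_id, n * length(tops)),
                 position = rep(seq_len(n), length(tops)),
                 model_id = rep(names(tops), each = n),
                 probs = rows)
}

toy_labels <- function(wt, protein_id = "p1", rsa = NULL) {
  data.table::data.table(protein_id = protein_id,
                         position = seq_along(wt), wt_aa = wt,
                         rsa = rsa %||% rep(0.1, length(wt)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flat-skill panel config useful for controlled experiments
flat_panel <- function(skill, ...) {
  prof <- function(id, ty) skill_profile(id, ty, uniform_skill(skill))
  panel_config(profiles = list(prof("struct_a", "structure"),
                               prof("struct_b", "structure"),
                               prof("seq_a", "sequence"),
                               prof("seq_b", "sequence")), ...)
}

# labels-only generation at a given total number of sites
sites_only <- function(config, n_sites, seed, len = 200L) {
  n_prot <- ceiling(n_sites / len)
  data.table::rbindlist(lapply(seq_len(n_prot), function(p)
    generate_protein(config, sprintf("sp%04d", p), len,
                     seed = resstack:::hash_seed(seed, "sites", p))$sites
  ))[seq_len(n_sites)]
}

# synthetic PDB ATOM line in strict fixed columns
pdb_line <- function(serial, name, resname, chain, resnum, x, y, z,
                     occ = 1, element = NULL, record = "ATOM", altloc = " ") {
  element <- element %||% substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resnum, x, y, z,
          occ, 0, element)
}
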