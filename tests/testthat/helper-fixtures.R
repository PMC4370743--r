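# Shared fixtures: all built in code, no stored data.

# fast engine settings for small test systems
quick_cfg <- function(...) {
  tbi_config(spacing = 1.2, pad_fine = 6, tol = 1e-5, born_spacing = 0.5,
             n_samples = 2, mode_budget = 12, ...)
}

# one charged sphere (atom + phosphate at the same point)
sphere_structure <- function(atom_radius = 2, charge = -1) {
  rna_structure(
    atoms = data.frame(element = "P", elety = "P", nt = 1L,
                       x = 0, y = 0, z = 0, radius = atom_radius,
                       stringsAsFactors = FALSE),
    phosphates = data.frame(nt = 1L, x = 0, y = 0, z = 0,
                            charge = charge, radius = atom_radius),
    resnames = "G", source = "toy")
}

# two phosphate spheres on the x axis
two_phos_structure <- function(d = 8, atom_radius = 2) {
  rna_structure(
    atoms = data.frame(element = c("P", "P"), elety = c("P", "P"),
                       nt = c(1L, 2L), x = c(0, d), y = 0, z = 0,
                       radius = atom_radius, stringsAsFactors = FALSE),
    phosphates = data.frame(nt = c(1L, 2L), x = c(0, d), y = 0, z = 0,
                            charge = -1, radius = atom_radius),
    resnames = c("G", "C"), source = "toy")
}

# a fixed-width PDB ATOM record (name in columns 13-16, element in 77-78)
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = substr(name, 1, 1)) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, alt, resn, chain, resno, x, y, z, occ, 0, element)
}

pdb_text <- function(lines) paste(c(lines, "END"), collapse = "\n")

# a fake mode evaluation (for assembling partition-sum inputs by hand)
fake_eval <- function(mode, dG, comps = c(u_self = 0, u_pol = 0, u_ele = 0,
                                          du_d = 0, ts_d = 0),
                      excess = c(Na = 0, Mg = 0, Cl = 0)) {
  structure(list(mode = as.integer(mode), n_bound = sum(mode == 1L),
                 dG_M = dG, comps = comps, prefactor = 0,
                 excess = excess, n_samples = 1L),
            class = "mode_evaluation")
}
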