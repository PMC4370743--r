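#' RNA structure with a coarse-grained charge model
#'
#' Container for the atoms of an RNA 3D structure together with the charge
#' model used throughout the package: one unit negative charge per phosphate,
#' placed on the P atom. The atom spheres (element-based van der Waals radii)
#' define the dielectric boundary and ion-exclusion surfaces; the phosphate
#' point charges are the fixed sources of the electrostatic problem.
#'
#' @param atoms data.frame with columns `element`, `elety` (atom name), `nt`
#'   (1-based nucleotide index), `x`, `y`, `z` (Angstrom), `radius` (Angstrom).
#' @param phosphates data.frame with columns `nt`, `x`, `y`, `z`, `charge`
#'   (elementary charges, -1 per phosphate).
#' @param resnames character vector of residue names, one per nucleotide.
#' @param source free-text provenance tag.
#' @return an object of class `rna_structure`.
#' @export
rna_structure <- function(atoms, phosphates, resnames, source = "user") {
  n <- length(resnames)
  if (n < 1) tbion_error("structure has no nucleotides", "tbion_empty_structure")
  if (nrow(phosphates) > n)
    tbion_error("more phosphates than nucleotides", "tbion_bad_argument")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    tbion_error("non-finite atom coordinates", "tbion_bad_argument")
  if (any(atoms$radius <= 0))
    tbion_error("atom radii must be positive", "tbion_bad_argument")
  structure(list(atoms = atoms, phosphates = phosphates,
                 n_nucleotides = n, resnames = resnames, source = source),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(sprintf("RNA structure (%s): %d nucleotides, %d atoms, %d phosphates\n",
              x$source, x$n_nucleotides, nrow(x$atoms), nrow(x$phosphates)))
  invisible(x)
}

# atoms as the (x, y, z, radius) matrix the grid kernels expect
atoms_xyzr <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z", "radius")])
}

phosphate_xyzq <- function(s) {
  cbind(as.matrix(s$phosphates[, c("x", "y", "z")]), q = s$phosphates$charge)
}

element_radius <- function(element, radii) {
  r <- radii[element]
  r[is.na(r)] <- radii["default"]
  unname(r)
}

RNA_RESIDUE_MAP <- c(
  A = "A", C = "C", G = "G", U = "U",
  RA = "A", RC = "C", RG = "G", RU = "U",
  ADE = "A", CYT = "C", GUA = "G", URA = "U", URI = "U"
)

#' Parse an RNA structure from PDB text or file
#'
#' Reads standard PDB ATOM records (first MODEL only) through the `bio3d`
#' reader and builds the coarse-grained charge model: residues are filtered
#' to standard ribonucleotides (A/C/G/U and common aliases), renumbered
#' contiguously 1..N in chain/file order, and every residue possessing a P
#' atom contributes one phosphate charge of -1e at the P position. Waters,
#' heteroatoms and unknown residues are dropped (with a warning for skipped
#' residues). Alternate locations keep the highest-occupancy copy, first on
#' tie.
#'
#' @param x either a path to a PDB file or a character scalar/vector holding
#'   PDB-format text.
#' @param config a [tbi_config()]; supplies the element radius table.
#' @return an [rna_structure()].
#' @examples
#' helix <- generate_aform_helix(2)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(helix, f)
#' s <- parse_pdb(f)
#' s$n_nucleotides
#' @export
parse_pdb <- function(x, config = tbi_config()) {
  config <- as_tbi_config(config)
  path <- x
  if (length(x) > 1 || grepl("\n", x[1]) || !file.exists(x[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(x) > 1) x else strsplit(x, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) tbion_error(paste0("no parseable ATOM records: ",
                                           conditionMessage(e)),
                                    "tbion_empty_structure"))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) tbion_error("no ATOM records", "tbion_empty_structure")

  resid <- toupper(trimws(at$resid))
  known <- resid %in% names(RNA_RESIDUE_MAP)
  skipped <- unique(resid[!known])
  if (length(skipped))
    warning("skipping non-RNA residue(s): ", paste(skipped, collapse = ", "))
  at <- at[known, , drop = FALSE]
  if (!nrow(at))
    tbion_error("all residues skipped; no standard ribonucleotides found",
                "tbion_empty_structure")

  # alternate locations: highest occupancy, first on tie
  occ <- at$o
  occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$insert, trimws(at$elety), sep = "|")
  ord <- order(factor(key, levels = unique(key)), -occ,
               seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert,
                             trimws(at$elety), sep = "|")), , drop = FALSE]
  # restore file order
  at <- at[order(as.numeric(rownames(at))), , drop = FALSE]

  reskey <- paste(at$chain, at$resno, at$insert, sep = "|")
  nt <- match(reskey, unique(reskey))
  elety <- trimws(at$elety)
  elesy <- trimws(at$elesy)
  element <- ifelse(!is.na(elesy) & nzchar(elesy), toupper(elesy),
                    toupper(substr(gsub("[^A-Za-z].*$", "", elety), 1, 1)))
  # two-letter symbols from elety like "MG" never occur in RNA ATOMs; keep 1st
  atoms <- data.frame(
    element = element, elety = elety, nt = nt,
    x = at$x, y = at$y, z = at$z,
    radius = element_radius(element, config$radii),
    stringsAsFactors = FALSE
  )
  resnames <- toupper(trimws(at$resid))[!duplicated(nt)]
  resnames <- unname(RNA_RESIDUE_MAP[resnames])

  isP <- atoms$elety == "P"
  ph <- atoms[isP, , drop = FALSE]
  ph <- ph[!duplicated(ph$nt), , drop = FALSE]
  phosphates <- data.frame(nt = ph$nt, x = ph$x, y = ph$y, z = ph$z,
                           charge = rep(-1, nrow(ph)), radius = ph$radius)
  rna_structure(atoms, phosphates, resnames, source = "pdb")
}

#' Write an RNA structure as a PDB file
#'
#' Serializes the atom records (via `bio3d::write.pdb`) so that generated
#' fixtures are valid PDB input for this package and other tools.
#'
#' @param s an [rna_structure()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(s, file) {
  a <- s$atoms
  chain <- rep("A", nrow(a))
  bio3d::write.pdb(pdb = NULL, file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$nt,
                   resid = s$resnames[a$nt],
                   eleno = seq_len(nrow(a)),
                   elety = a$elety,
                   chain = chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(file)
}

# idealized A-form template: one coarse-grained residue, cylindrical
# coordinates relative to the phosphate (radius A, phase deg, axial offset A)
AFORM_TEMPLATE <- data.frame(
  elety = c("P", "O5'", "C4'", "C1'", "N9", "C5", "C2"),
  element = c("P", "O", "C", "C", "N", "C", "C"),
  r = c(9.4, 9.1, 8.6, 7.2, 5.9, 4.4, 2.9),
  dphi = c(0, 9, 16, 26, 32, 41, 50),
  dz = c(0, -0.8, -1.2, -1.6, -1.9, -2.1, -2.3),
  stringsAsFactors = FALSE
)

#' Generate an idealized A-form RNA duplex
#'
#' Builds a coarse-grained A-form double helix of `n_basepairs` base pairs
#' (2 * n_basepairs nucleotides) from fibre-type parameters: helical rise
#' 2.81 Angstrom/bp, twist 32.7 deg/bp, phosphates at 9.4 Angstrom from the
#' helical axis. Each residue carries seven pseudo-atoms tracing the
#' backbone and base so the sphere union forms a realistic low-dielectric
#' body. The second strand is the exact dyad image of the first (180 deg
#' rotation about an axis perpendicular to the helix through its midpoint),
#' so the duplex is antiparallel and mirror-consistent by construction.
#' Output is deterministic.
#'
#' @param n_basepairs number of base pairs (>= 1).
#' @param rise helical rise per base pair, Angstrom.
#' @param twist helical twist per base pair, degrees.
#' @param p_radius phosphate distance from the helical axis, Angstrom.
#' @param config a [tbi_config()] for the radius table.
#' @return an [rna_structure()] with 2 * n_basepairs nucleotides and one
#'   phosphate per nucleotide.
#' @examples
#' h <- generate_aform_helix(12)
#' h$n_nucleotides # 24
#' @export
generate_aform_helix <- function(n_basepairs, rise = 2.81, twist = 32.7,
                                 p_radius = 9.4, config = tbi_config()) {
  if (!is.numeric(n_basepairs) || n_basepairs < 1)
    tbion_error("n_basepairs must be >= 1", "tbion_bad_argument")
  n <- as.integer(n_basepairs)
  config <- as_tbi_config(config)
  tpl <- AFORM_TEMPLATE
  tpl$r <- tpl$r * (p_radius / 9.4) # scale body with the phosphate radius

  one_strand <- function() {
    do.call(rbind, lapply(seq_len(n) - 1L, function(i) {
      phi <- (i * twist + tpl$dphi) * pi / 180
      data.frame(elety = tpl$elety, element = tpl$element,
                 nt = i + 1L,
                 x = tpl$r * cos(phi), y = tpl$r * sin(phi),
                 z = i * rise + tpl$dz, stringsAsFactors = FALSE)
    }))
  }
  s1 <- one_strand()
  zc <- (n - 1) * rise / 2
  # duplex dyad: 180 deg rotation about a horizontal axis through the helix
  # midpoint, phased so the strands sit 110 deg apart at equal height --
  # reproducing the A-form narrow/deep major groove (closest cross-strand
  # P-P about 8.7 A) and wide/shallow minor groove
  delta <- 110
  phi_d <- (delta + (n - 1) * twist) / 2 * pi / 180
  s2 <- s1
  s2$x <- cos(2 * phi_d) * s1$x + sin(2 * phi_d) * s1$y
  s2$y <- sin(2 * phi_d) * s1$x - cos(2 * phi_d) * s1$y
  s2$z <- 2 * zc - s2$z
  s2$nt <- s2$nt + n
  atoms <- rbind(s1, s2)
  atoms$radius <- element_radius(atoms$element, config$radii)
  isP <- atoms$elety == "P"
  phosphates <- data.frame(nt = atoms$nt[isP], x = atoms$x[isP],
                           y = atoms$y[isP], z = atoms$z[isP],
                           charge = rep(-1, sum(isP)),
                           radius = atoms$radius[isP])
  resnames <- rep(c("G", "C"), length.out = 2 * n)
  rna_structure(atoms, phosphates, resnames, source = "aform-helix")
}

#' Pairwise phosphate distance matrix
#'
#' @param s an [rna_structure()] with at least one phosphate.
#' @return a symmetric matrix of Euclidean distances (Angstrom) with zero
#'   diagonal, one row per phosphate in nucleotide order.
#' @export
pairwise_phosphate_distances <- function(s) {
  if (nrow(s$phosphates) < 1)
    tbion_error("structure has no phosphates", "tbion_bad_argument")
  m <- as.matrix(stats::dist(s$phosphates[, c("x", "y", "z")]))
  dimnames(m) <- NULL
  m
}
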