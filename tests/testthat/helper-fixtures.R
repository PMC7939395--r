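## Small fixtures built in code.

mol_water <- function() Molecule("water", "O")

mol_benzene <- function() {
  Molecule("benzene", rep("C", 6),
           cbind(1:6, c(2:6, 1), c(1, 2, 1, 2, 1, 2)))   # Kekule form
}

mol_cyclohexane <- function() {
  Molecule("cyclohexane", rep("C", 6), cbind(1:6, c(2:6, 1), 1))
}

mol_phenol <- function() {
  Molecule("phenol", c(rep("C", 6), "O"),
           rbind(cbind(1:6, c(2:6, 1), c(1, 2, 1, 2, 1, 2)),
                 c(1, 7, 1)))
}

## ethanol with an explicit hydroxyl hydrogen and 3-D coordinates
ethanol_conformer <- function() {
  m <- Molecule("ethanol", c("C", "C", "O", "H"),
                rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)))
  co <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.3, 0), c(3.1, 1.3, 0))
  list(molecule = m, coords = co)
}

## benzene ring coordinates in the xy plane
benzene_conformer <- function() {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  co <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  list(molecule = mol_benzene(), coords = co)
}

## minimal interface: one apolar contact and one N-H...O=C pair
mini_interface <- function() {
  mk <- cartwheel:::atom_row
  rec <- rbind(
    mk(1, "CB", "C", "LEU", "R", 1, c(0, 0, 0)),
    mk(2, "C", "C", "GLY", "R", 2, c(3, 0, 1)),
    mk(3, "O", "O", "GLY", "R", 2, c(3, 0, 2)))
  lig <- rbind(
    mk(4, "CB", "C", "ALA", "L", 1, c(0, 0, 3.5)),
    mk(5, "N", "N", "ALA", "L", 1, c(3, 0, 4.9)),
    mk(6, "H", "H", "ALA", "L", 1, c(3, 0, 3.9)))
  new("PDBStructure", atoms = rbind(rec, lig), modelId = 1L)
}

toy_pdb_text <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
  "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00 10.00           C",
  "ATOM      3  CB  ALA A   1       0.000   1.000   0.000  0.50 12.00           C",
  "END")

random_rigid <- function() {
  R <- cartwheel:::euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                                  runif(1, 0, 2 * pi))
  list(R = R, t = runif(3, -10, 10))
}
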