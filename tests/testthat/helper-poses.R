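# Build V2000 molfile text for tiny 3D test poses (explicit hydrogens
# where donor perception is under test). Charges written as M CHG lines.
make_molfile <- function(title, elements, xyz, bonds, charges = NULL,
                         target = "ache") {
  n <- length(elements)
  m <- nrow(bonds)
  at <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                xyz[, 1], xyz[, 2], xyz[, 3], elements)
  bd <- sprintf("%3d%3d%3d  0  0  0  0", bonds[, 1], bonds[, 2], bonds[, 3])
  lines <- c(title, "  mtscreen", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m),
             at, bd)
  if (!is.null(charges) && any(charges != 0)) {
    idx <- which(charges != 0)
    lines <- c(lines, sprintf("M  CHG%3d%s", length(idx),
                              paste(sprintf("%4d%4d", idx, charges[idx]),
                                    collapse = "")))
  }
  c(lines, "M  END", "> <target>", target, "", "$$$$")
}

write_pose_sdf <- function(..., path = tempfile(fileext = ".sdf")) {
  writeLines(unlist(list(...)), path)
  path
}

benzene_molfile <- function(target = "ache") {
  ang <- (0:5) * pi / 3
  make_molfile("benzene", rep("C", 6),
               cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
               cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)), target = target)
}

ethanol_molfile <- function(target = "ache") {
  make_molfile("ethanol", c("C", "C", "O", "H"),
               rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),
                     c(3.15, 1.25, 0)),
               rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)), target = target)
}

# N-protonated piperazine ring with one explicit H on the cation
piperazinium_molfile <- function(target = "ache") {
  make_molfile("pipz", c("N", "C", "C", "N", "C", "C", "H"),
               rbind(c(0, 0, 0), c(1.4, 0.3, 0), c(2.3, -0.8, 0),
                     c(1.9, -2.1, 0), c(0.5, -2.4, 0), c(-0.4, -1.3, 0),
                     c(0.2, 1.0, 0)),
               rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1),
                     c(5, 6, 1), c(6, 1, 1), c(1, 7, 1)),
               charges = c(1, 0, 0, 0, 0, 0, 0), target = target)
}

# A three-feature archetype used across the pharmacophore tests
archetype_features <- function() {
  data.frame(feature_type = c("aromatic_hydrophobic", "hbond_donor",
                              "hbond_acceptor"),
             x = c(0, 3.5, 7), y = c(0, 0.5, -0.5), z = 0,
             stringsAsFactors = FALSE)
}
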