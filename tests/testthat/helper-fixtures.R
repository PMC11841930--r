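# In-code fixtures: tiny FASTA/TSV/PDB files are written to tempdirs at
# test time; nothing binary is stored in the repository.

write_tmp_fasta <- function(text) {
  f <- tempfile(fileext = ".fasta")
  writeLines(text, f, sep = "")
  f
}

# Minimal PDB writer with correct fixed columns. `atoms` is a data.frame
# with columns elety, resno, x, y, z, b and optionally resid (3-letter;
# defaults to ALA); chain A throughout.
write_tmp_pdb <- function(atoms) {
  f <- tempfile(fileext = ".pdb")
  resid <- if (is.null(atoms$resid)) rep("ALA", nrow(atoms)) else atoms$resid
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            i, atoms$elety[i], resid[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i], 1.00, atoms$b[i])
  }, character(1))
  writeLines(c(lines, "END"), f)
  f
}

ca_atoms <- function(plddt, coords = NULL, aa = NULL) {
  n <- length(plddt)
  if (is.null(coords)) {
    coords <- cbind(3.8 * seq_len(n), sin(seq_len(n)), cos(seq_len(n)))
  }
  resid <- if (is.null(aa)) rep("ALA", n) else bio3d::aa123(aa)
  data.frame(elety = "CA", resno = seq_len(n), resid = resid,
             x = coords[, 1], y = coords[, 2], z = coords[, 3], b = plddt,
             stringsAsFactors = FALSE)
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# A small non-planar point cloud.
toy_points <- function(n = 6, seed = 11) {
  set.seed(seed)
  matrix(stats::rnorm(n * 3, sd = 3), ncol = 3)
}

# Tiny two-clade tree with labeled internals for parsimony examples.
four_leaf_tree <- function() {
  ape::read.tree(text = "((A:1,B:1)cladeAB:1,(C:1,D:1)cladeCD:1)root;")
}
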