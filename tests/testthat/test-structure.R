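test_that("pLDDT filtering removes low-confidence residues and is idempotent", {
  mod <- read_structure(write_tmp_pdb(ca_atoms(c(90, 45, 72))))
  filt <- filter_plddt(mod)
  expect_equal(filt$residues$resno, c(1, 3))
  expect_false(filt$excluded_entirely)
  expect_equal(filter_plddt(filt)$residues, filt$residues)

  all_hi <- read_structure(write_tmp_pdb(ca_atoms(c(60, 70, 80))))
  expect_equal(filter_plddt(all_hi)$residues, all_hi$residues)

  all_lo <- filter_plddt(read_structure(write_tmp_pdb(ca_atoms(c(10, 20, 30)))))
  expect_true(all_lo$excluded_entirely)
  expect_equal(nrow(all_lo$residues), 0)
})

test_that("kabsch is exact for identical and rigidly moved sets", {
  A <- toy_points(8)
  expect_lt(kabsch(A, A)$rmsd, 1e-8)

  B <- A %*% rot_z(pi / 2)
  B <- sweep(B, 2, c(5, -2, 1), `+`)
  sup <- kabsch(A, B)
  expect_lt(sup$rmsd, 1e-8)
  expect_true(sup$similar)
  # rotation is a proper orthonormal matrix
  expect_equal(t(sup$rotation) %*% sup$rotation, diag(3), tolerance = 1e-8)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  # transform maps B onto A
  expect_lt(max(abs(sweep(B %*% sup$rotation, 2, sup$translation, `+`) - A)),
            1e-6)

  expect_error(kabsch(A[1:2, ], A[1:2, ]), "3")
  expect_error(kabsch(A, A[1:4, ]), "mismatch")
})

test_that("rmsd is symmetric and invariant under rigid motions", {
  set.seed(21)
  A <- toy_points(10, seed = 21)
  B <- A + matrix(rnorm(30, sd = 0.5), ncol = 3)
  r1 <- kabsch(A, B)$rmsd
  expect_equal(kabsch(B, A)$rmsd, r1, tolerance = 1e-9)
  Bm <- sweep(B %*% rot_z(1.1), 2, c(-3, 7, 2), `+`)
  expect_lt(abs(kabsch(A, Bm)$rmsd - r1), 1e-8)
})

test_that("reflected sets are not matched by an improper rotation", {
  A <- toy_points(7, seed = 31)
  B <- A
  B[, 3] <- -B[, 3]                     # mirror a non-planar set
  sup <- kabsch(A, B)
  expect_gt(sup$rmsd, 1e-3)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
  set.seed(32)
  expect_equal(sup$rmsd, oracle_min_rmsd(A, B), tolerance = 1e-6)
})

test_that("sequence-paired superposition uses confident aligned residues", {
  set.seed(41)
  n <- 20
  aa <- sample(AA20_SET, n, replace = TRUE)
  coords <- cbind(3.8 * seq_len(n), sin(seq_len(n)) * 2, cos(seq_len(n)) * 2)
  a <- write_tmp_pdb(ca_atoms(rep(90, n), coords, aa = aa))
  coords_b <- sweep(coords %*% rot_z(0.7), 2, c(1, 2, 3), `+`)
  plddt_b <- rep(90, n); plddt_b[5:7] <- 30   # low-confidence stretch
  b <- write_tmp_pdb(ca_atoms(plddt_b, coords_b, aa = aa))
  sup <- superpose_models(read_structure(a), read_structure(b))
  expect_equal(sup$n_atoms, n - 3)
  # PDB coordinates carry 3 decimals, so a rigid copy is exact only to ~1e-3
  expect_lt(sup$rmsd, 0.01)
  expect_true(sup$similar)
})

test_that("interface residues are lifted and compared per role", {
  set.seed(51)
  stat2 <- random_aa_seq(200)
  irf9 <- random_aa_seq(300)
  substr(stat2, 174, 174) <- "F"
  for (p in c(274, 276, 283, 285)) {
    substr(irf9, p, p) <- c("274" = "L", "276" = "A", "283" = "F",
                            "285" = "Q")[[as.character(p)]]
  }
  refs <- list(STAT2 = list(id = "STAT2_ref", sequence = stat2),
               IRF9 = list(id = "IRF9_ref", sequence = irf9))

  # query identical to reference: 5/5
  rep <- check_interface(refs, list(STAT2 = list(id = "q1", sequence = stat2),
                                    IRF9 = list(id = "q2", sequence = irf9)))
  expect_equal(rep$conserved_count, 5)
  expect_equal(rep$denominator, 5)

  # F174A: 4/5 with the substitution visible in the report
  mut <- stat2; substr(mut, 174, 174) <- "A"
  rep <- check_interface(refs, list(STAT2 = list(id = "q1", sequence = mut),
                                    IRF9 = list(id = "q2", sequence = irf9)))
  expect_equal(rep$conserved_count, 4)
  e <- rep$entries[rep$entries$role == "STAT2", ]
  expect_equal(e$observed, "A")
  expect_false(e$conserved)

  # X at an interface position matches nothing
  mutx <- stat2; substr(mutx, 174, 174) <- "X"
  rep <- check_interface(refs, list(STAT2 = list(id = "q1", sequence = mutx),
                                    IRF9 = list(id = "q2", sequence = irf9)))
  expect_equal(rep$conserved_count, 4)

  # deletion spanning an interface position: not liftable, counted in the
  # denominator by default, excluded on request
  del <- paste0(substr(irf9, 1, 270), substr(irf9, 290, 300))
  rep <- check_interface(refs, list(STAT2 = list(id = "q1", sequence = stat2),
                                    IRF9 = list(id = "q2", sequence = del)))
  expect_lt(rep$conserved_count, 5)
  expect_equal(rep$denominator, 5)
  rep2 <- check_interface(refs, list(STAT2 = list(id = "q1", sequence = stat2),
                                     IRF9 = list(id = "q2", sequence = del)),
                          unliftable_counts = FALSE)
  expect_lt(rep2$denominator, 5)
})

test_that("ambiguous residues can be repaired from companions", {
  set.seed(61)
  base <- random_aa_seq(80)
  q <- base; substr(q, 40, 40) <- "X"
  comps <- data.frame(id = c("c1", "c2", "c3"),
                      sequence = c(base, base, base),
                      stringsAsFactors = FALSE)
  fixed <- sanitize_x(list(id = "q", sequence = q), comps)
  expect_equal(fixed$sequence, base)
  reps <- attr(fixed, "replacements")
  expect_equal(reps$position, 40)
  expect_equal(reps$to, substr(base, 40, 40))
  expect_equal(reps$support, 3)
})
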