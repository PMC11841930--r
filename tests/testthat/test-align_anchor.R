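test_that("identity and single-insertion alignments behave as expected", {
  a <- global_align("MKV", "MKV")
  expect_equal(a$aligned_ref, "MKV")
  expect_equal(a$aligned_query, "MKV")
  expect_true(all(!is.na(a$column_map$ref_pos)))

  a <- global_align("MKV", "MQKV")
  expect_equal(sum(strsplit(a$aligned_ref, "")[[1]] == "-"), 1)
  expect_equal(a$aligned_query, "MQKV")

  expect_error(global_align("", "MKV"), "empty")
  expect_error(global_align("MKV", ""), "empty")
})

test_that("the Gotoh oracle agrees with exhaustive alignment enumeration", {
  submat <- oracle_submat()
  set.seed(101)
  for (k in 1:25) {
    a <- random_aa_seq(sample(1:3, 1))
    b <- random_aa_seq(sample(1:3, 1))
    expect_equal(oracle_align_score(a, b, submat),
                 oracle_align_score_exhaustive(a, b, submat),
                 info = paste(a, b))
  }
})

test_that("alignment scores equal the independent DP oracle on random pairs", {
  submat <- oracle_submat()
  set.seed(202)
  for (k in 1:60) {
    a <- random_aa_seq(sample(1:8, 1), alphabet = c(AA20_SET, "X"))
    b <- random_aa_seq(sample(1:8, 1), alphabet = c(AA20_SET, "X"))
    expect_equal(global_align(a, b)$score,
                 oracle_align_score(a, b, submat),
                 info = paste(a, b))
  }
})

test_that("region lifting handles identity, insertions and deletions", {
  ref <- list(id = "ref", sequence = "MKVDLENWAR")
  # identity lift
  lr <- lift_region(global_align(ref, "MKVDLENWAR"),
                    region_annotation("r", "ref", 3, 5))
  expect_equal(c(lr$q_start, lr$q_end), c(3, 5))
  expect_equal(lr$status, "complete")
  expect_equal(lr$subsequence, "VDL")

  # 2-residue insertion before the region shifts coordinates by 2
  lr <- lift_region(global_align(ref, "MKGGVDLENWAR"),
                    region_annotation("r", "ref", 3, 5))
  expect_equal(c(lr$q_start, lr$q_end), c(5, 7))
  expect_equal(lr$status, "complete")
  expect_equal(lr$subsequence, "VDL")

  # region deleted in the query
  lr <- lift_region(global_align(ref, "MKNWAR"),
                    region_annotation("r", "ref", 4, 5))
  expect_equal(lr$status, "missing")
  expect_true(is.na(lr$q_start))

  expect_error(lift_region(global_align(ref, "MKVDLENWAR"),
                           region_annotation("r", "ref", 5, 99)),
               "exceeds")
})

test_that("lift is the identity for indel-free pairs", {
  set.seed(77)
  for (k in 1:10) {
    n <- 40
    ref_seq <- random_aa_seq(n)
    # substitutions only, no indels
    ch <- strsplit(ref_seq, "")[[1]]
    idx <- sample(n, 5)
    ch[idx] <- sample(AA20_SET, 5, replace = TRUE)
    q <- paste(ch, collapse = "")
    aln <- global_align(ref_seq, q)
    for (st in c(1, 10, 25)) {
      lr <- lift_region(aln, list(name = "w", ref_id = "ref",
                                  start = st, end = st + 8))
      # identical-length ungapped pairs must lift one-to-one
      if (!grepl("-", aln$aligned_ref, fixed = TRUE) &&
          !grepl("-", aln$aligned_query, fixed = TRUE)) {
        expect_equal(c(lr$q_start, lr$q_end), c(st, st + 8))
        expect_equal(lr$status, "complete")
      }
    }
  }
})

test_that("lifting recovers planted windows on simulated families", {
  fx <- default_fixture(seed = 19)
  for (fam in c("IRF5", "IRF6")) {
    recs <- fx$records[fx$records$subfamily == fam, , drop = FALSE]
    ref <- recs[recs$id == fx$reference_ids[[fam]], , drop = FALSE]
    lifted <- lift_regions_all(ref, recs, fx$regions[[fam]])
    truth <- fx$truths[[fam]]
    for (i in seq_len(nrow(lifted))) {
      sp <- recs$species[match(lifted$query_id[i], recs$id)]
      tw <- truth$windows[[sp]][[lifted$name[i]]]
      expect_equal(lifted$status[i], "complete")
      expect_equal(lifted$subsequence[i], tw$sequence,
                   info = paste(fam, sp, lifted$name[i]))
    }
  }
})
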