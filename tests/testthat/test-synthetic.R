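zero_blen_config <- function(seed = 1) {
  tr <- ape::read.tree(text = "((A:0,B:0)ab:0,(C:0,D:0)cd:0)root;")
  sim_config(tr, root_length = 120L,
             windows = list(signature_window_def(30L)),
             subfamily = "TEST",
             clade_map = c(A = "g1", B = "g1", C = "g2", D = "g2"),
             seed = seed)
}

test_that("zero branch lengths and no indels reproduce the root everywhere", {
  fam <- simulate_family(zero_blen_config())
  expect_equal(length(unique(fam$records$sequence)), 1)
  expect_equal(fam$records$sequence[1], fam$truth$root_sequence)
})

test_that("planted transitions are deterministic and clade-wide", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)ab:0.1,(C:0.1,D:0.1)cd:0.1)root;")
  cfg <- sim_config(tr, root_length = 150L,
                    windows = list(signature_window_def(40L)),
                    transitions = list(list(child = "cd", window = "signature",
                                            to = "FDG")),
                    subfamily = "TEST",
                    clade_map = c(A = "g", B = "g", C = "g", D = "g"),
                    seed = 9)
  fam <- simulate_family(cfg)
  motifs <- vapply(fam$truth$windows, function(w) w$signature$sequence,
                   character(1))
  expect_equal(unname(motifs[c("A", "B")]), c("YDG", "YDG"))
  expect_equal(unname(motifs[c("C", "D")]), c("FDG", "FDG"))
  expect_equal(length(fam$truth$transitions), 1)
  expect_equal(fam$truth$transitions[[1]]$from, "YDG")
})

test_that("incompatible transition motifs are rejected at config time", {
  tr <- ape::read.tree(text = "((A:1,B:1)ab:1,C:1)root;")
  expect_error(
    sim_config(tr, root_length = 100L,
               windows = list(signature_window_def(10L)),
               transitions = list(list(child = "ab", window = "signature",
                                       to = "FD"))),
    "incompatible")
  expect_error(
    sim_config(tr, root_length = 100L,
               windows = list(signature_window_def(10L)),
               transitions = list(list(child = "nope", window = "signature",
                                       to = "FDG"))),
    "nope")
  expect_error(
    sim_config(tr, root_length = 100L,
               windows = list(signature_window_def(10L),
                              signature_window_def(11L))),
    "overlap")
})

test_that("the same seed is byte-identical and different seeds differ", {
  fx1 <- default_fixture(seed = 4)
  fx2 <- default_fixture(seed = 4)
  expect_identical(fx1$records, fx2$records)
  fx3 <- default_fixture(seed = 5)
  expect_false(identical(fx1$records$sequence, fx3$records$sequence))
})

test_that("emitted fixtures are loadable and truth round-trips", {
  fx <- default_fixture(seed = 2)
  d <- tempfile()
  paths <- emit_fixture(fx$records, fx$truths$IRF5, fx$tree, d)
  recs <- read_fasta(paths[["fasta"]])
  expect_equal(nrow(recs), nrow(fx$records))
  expect_identical(recs$sequence, fx$records$sequence)
  md <- read_metadata(paths[["metadata"]])
  joined <- join_metadata(recs, md)
  expect_equal(joined$taxon_group, fx$records$taxon_group)
  tr <- read_taxonomy(paths[["tree"]])
  expect_setequal(tr$tip.label, unique(fx$records$species))
  truth <- read_truth(paths[["truth"]])
  expect_equal(truth$schema_version, 1L)
  expect_equal(truth$root_sequence, fx$truths$IRF5$root_sequence)
  expect_equal(truth$windows$mammal_01$NES$start,
               fx$truths$IRF5$windows$mammal_01$NES$start)
})

test_that("metadata taxon groups match the taxonomy clades", {
  fx <- default_fixture(seed = 8)
  tr <- fx$tree
  for (grp in c("Mammalia", "Chondrichthyes", "Palaeognathae", "Galloanserae")) {
    members <- fx$metadata$species[fx$metadata$taxon_group == grp &
                                     fx$metadata$subfamily == "IRF5"]
    node <- which(tr$node.label == grp) + length(tr$tip.label)
    in_clade <- ape::extract.clade(tr, node)$tip.label
    expect_setequal(members, in_clade)
  }
})

test_that("indels never land inside anchored windows", {
  fx <- default_fixture(seed = 13, indel_rate = 0.02)  # indel-rich
  truth <- fx$truths$IRF5
  recs <- fx$records[fx$records$subfamily == "IRF5", ]
  for (sp in names(truth$windows)) {
    seqs <- recs$sequence[recs$species == sp]
    for (w in truth$windows[[sp]]) {
      expect_equal(substr(seqs, w$start, w$end), w$sequence,
                   info = paste(sp, w$name))
      expect_equal(w$end - w$start + 1, nchar(w$sequence))
    }
  }
})
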