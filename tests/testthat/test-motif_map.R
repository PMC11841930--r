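lr <- function(seq, status = "complete", id = "q", start = 60) {
  list(query_id = id, name = "signature", q_start = start,
       q_end = start + nchar(seq) - 1, status = status, subsequence = seq)
}

test_that("signature motifs classify into the named set or other", {
  expect_equal(extract_signature(lr("YDG"))$class_label, "YDG")
  expect_equal(extract_signature(lr("FDG"))$class_label, "FDG")
  expect_equal(extract_signature(lr("WDG"))$class_label, "other")
  a <- extract_signature(lr("YD", status = "partial"))
  expect_equal(a$class_label, "other")
  expect_true(a$missing)
})

test_that("clade tallies count each species once and respect nesting", {
  tree <- four_leaf_tree()
  asg <- data.frame(species = c("A", "B", "C"),
                    class_label = c("YDG", "YDG", "FDG"),
                    stringsAsFactors = FALSE)
  t1 <- tally_by_clade(asg, tree, c("root", "cladeAB", "cladeCD"))
  expect_equal(t1$YDG, c(2, 2, 0))
  expect_equal(t1$FDG, c(1, 0, 1))
  expect_equal(t1$n_species, c(3, 2, 1))
  # empty clade gives an all-zero row; D has no assignment
  expect_equal(sum(unlist(t1[t1$clade == "cladeCD",
                             c("YDG", "LDG", "VDG", "other")])), 0)
  expect_error(tally_by_clade(
    data.frame(species = "Z", class_label = "YDG"), tree, "root"), "Z")
})

test_that("parsimony solves forced and degenerate cases", {
  tree <- four_leaf_tree()
  # two equal-sized clades: one change, but its placement (and the root
  # state) is ambiguous - exactly two optimal labelings
  res <- parsimony_states(tree, c(A = "YDG", B = "YDG", C = "FDG", D = "FDG"))
  expect_equal(res$min_changes, 1)
  expect_false(res$is_unique)
  expect_equal(res$n_optimal_labelings, 2)
  expect_equal(nrow(res$transitions), 1)
  expect_true(res$transitions$child %in% c("cladeAB", "cladeCD"))

  # a single derived leaf forces the root and makes the history unique
  res <- parsimony_states(tree, c(A = "YDG", B = "YDG", C = "YDG", D = "FDG"))
  expect_equal(res$min_changes, 1)
  expect_true(res$is_unique)
  expect_equal(res$transitions$child, "D")
  expect_equal(res$transitions$to, "FDG")

  res <- parsimony_states(tree, c(A = "YDG", B = "YDG", C = "YDG", D = "YDG"))
  expect_equal(res$min_changes, 0)
  expect_equal(nrow(res$transitions), 0)

  expect_error(parsimony_states(tree, c(A = "YDG", B = "YDG", C = "FDG")),
               "D")
})

test_that("min_changes equals exhaustive enumeration on random trees", {
  set.seed(303)
  for (k in 1:20) {
    tr <- random_rooted_tree(6)
    ls <- setNames(sample(c("Y", "F", "L"), 6, replace = TRUE), tr$tip.label)
    res <- parsimony_states(tr, ls)
    orc <- oracle_parsimony(tr, ls)
    expect_equal(res$min_changes, orc$min_changes, info = k)
    expect_equal(res$is_unique, orc$n_optimal == 1, info = k)
    expect_equal(res$n_optimal_labelings, orc$n_optimal, info = k)
    expect_gte(res$min_changes, length(unique(ls)) - 1)
  }
})

test_that("min_changes is invariant to leaf order and matches phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(304)
  for (k in 1:10) {
    tr <- random_rooted_tree(7)
    ls <- setNames(sample(c("a", "b", "c"), 7, replace = TRUE), tr$tip.label)
    res <- parsimony_states(tr, ls)
    # shuffle leaf order via the names
    perm <- sample(names(ls))
    expect_equal(parsimony_states(tr, ls[perm])$min_changes, res$min_changes)
    # independent cross-check
    dat <- phangorn::phyDat(matrix(ls[tr$tip.label], ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("a", "b", "c"))
    expect_equal(res$min_changes,
                 as.integer(phangorn::parsimony(ape::unroot(tr), dat)))
  }
})

test_that("multifurcating trees are handled (Hartigan generalization)", {
  tr <- ape::read.tree(text = "(A:1,B:1,C:1,(D:1,E:1)de:1)root;")
  res <- parsimony_states(tr, c(A = "Y", B = "Y", C = "Y", D = "F", E = "F"))
  expect_equal(res$min_changes, 1)
  expect_equal(res$transitions$child, "de")
  orc <- oracle_parsimony(tr, c(A = "Y", B = "Y", C = "Y", D = "F", E = "F"))
  expect_equal(res$min_changes, orc$min_changes)
})

test_that("planted transitions are recovered exactly on the fixture", {
  fx <- default_fixture(seed = 5)
  recs <- fx$records[fx$records$subfamily == "IRF5", , drop = FALSE]
  ref <- recs[recs$id == fx$reference_ids[["IRF5"]], , drop = FALSE]
  lifted <- lift_regions_all(ref, recs, fx$regions$IRF5)
  lifted$species <- recs$species[match(lifted$query_id, recs$id)]
  asg <- assign_signatures(lifted)
  res <- parsimony_states(fx$tree, setNames(asg$class_label, asg$species))
  expect_equal(res$min_changes, 3)
  expect_true(res$is_unique)
  got <- res$transitions[order(res$transitions$child),
                         c("child", "from", "to")]
  want <- data.frame(child = c("Neoaves", "Passeridae", "Passeriformes"),
                     from = c("YDG", "LDG", "FDG"),
                     to = c("FDG", "VDG", "LDG"), stringsAsFactors = FALSE)
  rownames(got) <- NULL
  expect_equal(got, want)
})
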