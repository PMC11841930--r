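# Independent oracles used to validate the package implementations.
# These are deliberately written as direct, naive transliterations of the
# definitions, sharing no code with the package internals.

HYDRO_SET <- c("L", "I", "V", "F", "M")
AA20_SET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa_seq <- function(n, alphabet = AA20_SET) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force NES consensus enumeration: every start x every spacer
# combination, each anchor checked one character at a time.
oracle_scan_nes <- function(sequence) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  out <- list()
  for (i in seq_len(max(n, 0))) {
    for (s1 in c(2L, 3L)) {
      for (s2 in c(2L, 3L)) {
        p2 <- i + s1 + 1L
        p3 <- p2 + s2 + 1L
        p4 <- p3 + 2L
        if (p4 > n) next
        if (ch[i] %in% HYDRO_SET && ch[p2] %in% HYDRO_SET &&
            ch[p3] %in% HYDRO_SET && ch[p4] %in% HYDRO_SET) {
          out[[length(out) + 1L]] <- c(start = i, end = p4,
                                       spacer1 = s1, spacer2 = s2)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      spacer1 = integer(), spacer2 = integer()))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$start, df$spacer1, df$spacer2), , drop = FALSE]
}

# Gotoh-style global alignment score in plain R: affine gaps, a gap of
# length k costing open + k * extend, terminal gaps penalized.
oracle_align_score <- function(a, b, submat, open = 10, extend = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  n <- length(ac); m <- length(bc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # match state
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[ac[i], bc[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend,
                             Y[i, j + 1] - open - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend,
                             X[i + 1, j] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive enumeration of every monotone alignment (for tiny inputs only):
# validates the Gotoh oracle itself.
oracle_align_score_exhaustive <- function(a, b, submat, open = 10, extend = 1) {
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > length(ac) && j > length(bc)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      rec(i + 1, j + 1, score + submat[ac[i], bc[j]], "m")
    }
    if (i <= length(ac)) {
      pen <- if (prev == "x") extend else open + extend
      rec(i + 1, j, score - pen, "x")
    }
    if (j <= length(bc)) {
      pen <- if (prev == "y") extend else open + extend
      rec(i, j + 1, score - pen, "y")
    }
  }
  rec(1, 1, 0, "m")
  best
}

# BLOSUM62 with X scoring 0, fetched independently of the package cache.
oracle_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62[c(AA20_SET, "X"), c(AA20_SET, "X")]
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

# Exhaustive parsimony: enumerate every internal labeling, count changes.
oracle_parsimony <- function(tree, leaf_states) {
  states <- sort(unique(as.character(leaf_states)))
  ntip <- length(tree$tip.label)
  n_internal <- tree$Nnode
  grid <- do.call(expand.grid,
                  c(rep(list(states), n_internal), stringsAsFactors = FALSE))
  assign_tip <- as.character(leaf_states[tree$tip.label])
  best <- Inf
  n_best <- 0L
  for (g in seq_len(nrow(grid))) {
    lab <- c(assign_tip, unlist(grid[g, ], use.names = FALSE))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (changes < best) { best <- changes; n_best <- 1L }
    else if (changes == best) n_best <- n_best + 1L
  }
  list(min_changes = best, n_optimal = n_best)
}

random_rooted_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  tr
}

# Numeric-optimization RMSD oracle: minimize over proper rotations
# parameterized by Euler angles, translation removed by centering.
oracle_min_rmsd <- function(A, B, n_starts = 20) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  rotmat <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(p) {
    R <- rotmat(p)
    sqrt(mean(rowSums((A0 - B0 %*% R)^2)))
  }
  best <- Inf
  for (k in seq_len(n_starts)) {
    p0 <- stats::runif(3, 0, 2 * pi)
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}
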