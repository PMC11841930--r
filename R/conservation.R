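# Per-column conservation profiles and sequence-logo data.
#
# Information content per column is log2(20) minus the Shannon entropy of the
# residue distribution over non-gap residues, with no background-composition
# adjustment and no small-sample correction - the convention of an
# unadjusted protein sequence logo. Gap handling: frequencies are computed
# over non-gap characters and the gap fraction is reported separately; stack
# height scaling by occupancy is a rendering concern, not a data concern.

#' Per-column frequency profile of an aligned region
#'
#' @param region_sequences Character vector of equal-length strings over the
#'   amino-acid alphabet plus \code{-} (gap) and \code{X}.
#' @param group Optional group label (e.g. a taxon group) carried in the
#'   result.
#' @return An object of class \code{frequency_profile}: \code{freq} (residues
#'   x positions matrix of relative frequencies over non-gap characters),
#'   \code{gap_fraction}, \code{occupancy}, \code{ic_bits} (NA for all-gap
#'   columns, which are also flagged in \code{all_gap}), \code{n_sequences},
#'   \code{length}, \code{group}.
#' @export
column_profile <- function(region_sequences, group = NA_character_) {
  n <- length(region_sequences)
  if (n == 0L) stop("no sequences")
  region_sequences <- toupper(region_sequences)
  lens <- nchar(region_sequences)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("sequences have unequal lengths: %s",
                 paste(sort(unique(lens)), collapse = ", ")))
  }
  L <- lens[1]
  for (s in region_sequences) check_sequence_alphabet(s, allow_gap = TRUE)
  chars <- matrix(unlist(strsplit(region_sequences, "", fixed = TRUE)),
                  nrow = n, ncol = L, byrow = TRUE)
  residues <- AA_ALPHABET
  freq <- matrix(0, nrow = length(residues), ncol = L,
                 dimnames = list(residues, NULL))
  gap_fraction <- numeric(L)
  ic_bits <- rep(NA_real_, L)
  for (j in seq_len(L)) {
    col <- chars[, j]
    gaps <- col == "-"
    gap_fraction[j] <- mean(gaps)
    obs <- col[!gaps]
    if (length(obs) == 0L) next                     # all-gap: ic undefined
    counts <- table(factor(obs, levels = residues))
    p <- as.numeric(counts) / length(obs)
    freq[, j] <- p
    nz <- p[p > 0]
    ic_bits[j] <- log2(20) + sum(nz * log2(nz))
  }
  structure(list(freq = freq, gap_fraction = gap_fraction,
                 occupancy = 1 - gap_fraction, ic_bits = ic_bits,
                 all_gap = gap_fraction == 1, n_sequences = n,
                 length = L, group = group),
            class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat(sprintf("frequency_profile: %d columns, %d sequences%s\n", x$length,
              x$n_sequences,
              if (!is.na(x$group)) sprintf(" [%s]", x$group) else ""))
  cat(sprintf("  IC (bits): %s\n",
              paste(sprintf("%.2f", x$ic_bits), collapse = " ")))
  invisible(x)
}

#' Count distinct sequences in a region set
#'
#' Case-insensitive exact distinct count; used e.g. to show that every
#' mammalian serine-rich region in a family is one and the same sequence.
#'
#' @param region_sequences Character vector (may be empty).
#' @return Integer count of distinct strings.
#' @export
count_distinct <- function(region_sequences) {
  length(unique(toupper(region_sequences)))
}

#' Export a frequency profile as a TSV logo matrix
#'
#' One row per column: position, the frequency of each residue, information
#' content and gap fraction. Round-trips losslessly through
#' [import_logo_data()].
#'
#' @param profile A \code{frequency_profile}.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
export_logo_data <- function(profile, path) {
  stopifnot(inherits(profile, "frequency_profile"))
  df <- data.frame(position = seq_len(profile$length))
  if (profile$length == 0L) df <- data.frame(position = integer())
  fr <- t(profile$freq)
  for (res in rownames(profile$freq)) df[[res]] <- fr[, res]
  df$ic_bits <- profile$ic_bits
  df$gap_fraction <- profile$gap_fraction
  df$n_sequences <- rep(profile$n_sequences, nrow(df))
  write_tsv(format(df, digits = 17, scientific = FALSE, trim = TRUE), path)
  invisible(path)
}

#' Re-import a logo matrix written by [export_logo_data()]
#'
#' @param path TSV path.
#' @return A \code{frequency_profile} (without the original group label).
#' @export
import_logo_data <- function(path) {
  df <- read_tsv(path)
  residues <- AA_ALPHABET
  L <- nrow(df)
  freq <- matrix(0, nrow = length(residues), ncol = L,
                 dimnames = list(residues, NULL))
  for (res in residues) freq[res, ] <- as.numeric(df[[res]])
  gap_fraction <- as.numeric(df$gap_fraction)
  if (L == 0L) gap_fraction <- numeric(0)
  structure(list(freq = freq, gap_fraction = gap_fraction,
                 occupancy = 1 - gap_fraction,
                 ic_bits = as.numeric(df$ic_bits),
                 all_gap = gap_fraction == 1,
                 n_sequences = if (L > 0L) df$n_sequences[1] else 0L,
                 length = L, group = NA_character_),
            class = "frequency_profile")
}

#' Group region sequences by a metadata key and profile each group
#'
#' @param lifted_table Data.frame from [lift_regions_all()] joined with
#'   metadata (must carry \code{taxon_group}).
#' @param region_name Which region to profile.
#' @return Named list of \code{frequency_profile}s, one per taxon group,
#'   built from complete lifts of equal length only (lifts whose length
#'   differs from the group's modal length are dropped with a warning).
#' @export
profile_by_group <- function(lifted_table, region_name) {
  sel <- lifted_table[lifted_table$name == region_name &
                        lifted_table$status == "complete", , drop = FALSE]
  if (nrow(sel) == 0L) return(list())
  out <- list()
  for (grp in sort(unique(sel$taxon_group))) {
    seqs <- sel$subsequence[sel$taxon_group == grp]
    lens <- nchar(seqs)
    modal <- as.integer(names(which.max(table(lens))))
    if (any(lens != modal)) {
      warning(sprintf("%s/%s: dropping %d sequence(s) with non-modal length",
                      region_name, grp, sum(lens != modal)))
      seqs <- seqs[lens == modal]
    }
    out[[grp]] <- column_profile(seqs, group = grp)
  }
  out
}
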