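# Nuclear export signal (NES) consensus scanning.
#
# The leucine-rich NES consensus is Phi1-X(2,3)-Phi2-X(2,3)-Phi3-X-Phi4 with
# Phi in {L, I, V, F, M} and X any residue. Every start position and every
# spacer decomposition is reported, including overlapping matches, so no
# information is lost; consumers may deduplicate by span.

#' Scan a protein sequence for NES consensus matches
#'
#' Enumerates every match of the hydrophobic-anchored consensus
#' \eqn{\Phi_1 X_{2,3} \Phi_2 X_{2,3} \Phi_3 X \Phi_4},
#' \eqn{\Phi \in \{L,I,V,F,M\}}. The unknown residue \code{X} never counts as
#' hydrophobic. Match length is spacer1 + spacer2 + 5, i.e. 9-11 residues.
#'
#' @param sequence Protein sequence string (or a protein record).
#' @return A data.frame sorted by (start, spacer1, spacer2) with columns
#'   \code{start}, \code{end}, \code{spacer1}, \code{spacer2}, \code{a1}-
#'   \code{a4} (anchor positions) and \code{matched} (the matched substring).
#'   Zero rows when there is no match.
#' @export
scan_nes <- function(sequence) {
  rec <- as_protein_record(sequence)
  s <- rec$sequence
  n <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      spacer1 = integer(), spacer2 = integer(),
                      a1 = integer(), a2 = integer(), a3 = integer(),
                      a4 = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  if (n < 9L) return(empty)
  chars <- seq_chars(s)
  hydro <- chars %in% HYDROPHOBIC

  rows <- empty
  for (s1 in 2:3) {
    for (s2 in 2:3) {
      span <- s1 + s2 + 5L          # match length
      last <- n - span + 1L
      if (last < 1L) next
      p1 <- seq_len(last)
      p2 <- p1 + s1 + 1L
      p3 <- p2 + s2 + 1L
      p4 <- p3 + 2L
      hit <- hydro[p1] & hydro[p2] & hydro[p3] & hydro[p4]
      if (!any(hit)) next
      p1 <- p1[hit]
      rows <- rbind(rows, data.frame(
        start = p1, end = p1 + span - 1L,
        spacer1 = s1, spacer2 = s2,
        a1 = p1, a2 = p1 + s1 + 1L, a3 = p1 + s1 + s2 + 2L,
        a4 = p1 + s1 + s2 + 4L,
        matched = substring(s, p1, p1 + span - 1L),
        stringsAsFactors = FALSE))
    }
  }
  rows[order(rows$start, rows$spacer1, rows$spacer2), , drop = FALSE]
}

#' Check an annotated window against NES consensus matches
#'
#' A window conforms when at least one consensus match lies entirely inside
#' it. The annotated reference window (12 residues in the human IRF5 NES)
#' is wider than the longest consensus match (11), so containment - not span
#' equality - is the test. Matches that only overlap the window boundary are
#' reported separately.
#'
#' @param matches Match table from [scan_nes()] for the same sequence.
#' @param lifted A \code{lifted_region} (status must not be \code{missing}).
#' @return A list: \code{conforms} (logical), \code{n_contained},
#'   \code{n_overlapping}, and the corresponding match-table subsets
#'   \code{contained} and \code{overlapping}.
#' @export
window_check <- function(matches, lifted) {
  if (identical(lifted$status, "missing")) {
    stop("cannot check a missing region window")
  }
  qs <- lifted$q_start
  qe <- lifted$q_end
  contained <- matches$start >= qs & matches$end <= qe
  overlapping <- !contained & matches$start <= qe & matches$end >= qs
  list(conforms = any(contained),
       n_contained = sum(contained),
       n_overlapping = sum(overlapping),
       contained = matches[contained, , drop = FALSE],
       overlapping = matches[overlapping, , drop = FALSE])
}

#' Report residues at critical window-relative positions
#'
#' Some windows carry experimentally established critical residues (e.g. the
#' two hydrophobic positions essential for IRF5 nuclear export). Their
#' window-relative offsets are supplied by the user; this reports the residue
#' found at each offset and whether it is hydrophobic.
#'
#' @param lifted A complete \code{lifted_region}.
#' @param offsets Integer vector of 1-based offsets within the window.
#' @return Data.frame with \code{offset}, \code{position} (query coordinate),
#'   \code{residue}, \code{hydrophobic}.
#' @export
critical_residues <- function(lifted, offsets) {
  if (!identical(lifted$status, "complete")) {
    stop("critical-residue check requires a completely lifted window")
  }
  width <- nchar(lifted$subsequence)
  if (any(offsets < 1L | offsets > width)) {
    stop("offset outside window")
  }
  res <- substring(lifted$subsequence, offsets, offsets)
  data.frame(offset = as.integer(offsets),
             position = lifted$q_start + as.integer(offsets) - 1L,
             residue = res,
             hydrophobic = res %in% HYDROPHOBIC,
             stringsAsFactors = FALSE)
}

#' Scan many records and report matches relative to lifted windows
#'
#' @param records Data.frame of protein records.
#' @param lifted_table Optional data.frame from [lift_regions_all()]; when
#'   given, each match is flagged \code{in_window} if contained in any
#'   non-missing lifted window of its sequence.
#' @return Data.frame with columns \code{seq_id}, \code{start}, \code{end},
#'   \code{spacer1}, \code{spacer2}, \code{matched}, \code{in_window}.
#' @export
scan_nes_all <- function(records, lifted_table = NULL) {
  out <- list()
  for (i in seq_len(nrow(records))) {
    m <- scan_nes(records$sequence[i])
    if (nrow(m) == 0L) next
    in_window <- rep(FALSE, nrow(m))
    if (!is.null(lifted_table)) {
      wins <- lifted_table[lifted_table$query_id == records$id[i] &
                             lifted_table$status != "missing", , drop = FALSE]
      for (j in seq_len(nrow(wins))) {
        in_window <- in_window |
          (m$start >= wins$q_start[j] & m$end <= wins$q_end[j])
      }
    }
    out[[length(out) + 1L]] <- data.frame(
      seq_id = records$id[i], m[, c("start", "end", "spacer1", "spacer2", "matched")],
      in_window = in_window, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(), start = integer(), end = integer(),
                      spacer1 = integer(), spacer2 = integer(),
                      matched = character(), in_window = logical(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
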