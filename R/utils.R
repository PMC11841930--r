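# Shared constants and small internal helpers.

# 20 standard residues; X is tolerated as an unknown that matches nothing.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA20, "X")
HYDROPHOBIC <- c("L", "I", "V", "F", "M")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept a protein record as a one-row data.frame, a list, or a bare string.
as_protein_record <- function(x, id = "seq") {
  if (is.character(x) && length(x) == 1L && is.null(names(x))) {
    return(list(id = id, sequence = toupper(x)))
  }
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(list(id = as.character(x$id), sequence = toupper(as.character(x$sequence))))
  }
  if (is.list(x)) {
    return(list(id = as.character(x$id %||% id), sequence = toupper(as.character(x$sequence))))
  }
  stop("cannot interpret input as a protein record")
}

seq_chars <- function(sequence) strsplit(sequence, "", fixed = TRUE)[[1]]

check_sequence_alphabet <- function(sequence, id = "sequence", allow_gap = FALSE) {
  ok <- AA_ALPHABET
  if (allow_gap) ok <- c(ok, "-")
  bad <- setdiff(unique(seq_chars(sequence)), ok)
  if (length(bad) > 0L) {
    stop(sprintf("invalid characters in %s: %s", id, paste(sort(bad), collapse = ", ")))
  }
  invisible(TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
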