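# Unit-cost substitution matrix over the IUPAC alphabet: identical letters
# score 0, everything else -1; 'N' mismatches everything including itself.
unit_submat <- function() {
  ab <- iupac_alphabet()
  m <- matrix(-1, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- 0
  m["N", "N"] <- -1
  m
}

#' Center-star multiple alignment
#'
#' Aligns short homologous sequences (e.g. predicted amplicons) around the
#' center sequence, defined as the sequence minimizing the total pairwise
#' edit distance to all others (ties broken by lowest input index). Every
#' other sequence is globally aligned to the center with unit costs and the
#' pairwise gaps are merged under "once a gap, always a gap".
#'
#' @param seqs Character vector of DNA sequences (>= 1); names become row ids.
#' @return An `msa` object: list with `ids` and equal-length gapped `rows`.
#'   Removing the gaps from row *i* reproduces input *i*.
#' @export
center_star_align <- function(seqs) {
  if (length(seqs) == 0) stop("no sequences to align", call. = FALSE)
  seqs <- normalize_dna(seqs)
  ids <- if (is.null(names(seqs))) paste0("seq_", seq_along(seqs)) else names(seqs)
  if (length(seqs) == 1) {
    return(structure(list(ids = ids, rows = unname(seqs)), class = "msa"))
  }
  ss <- Biostrings::DNAStringSet(seqs)
  dmat <- as.matrix(Biostrings::stringDist(ss, method = "levenshtein"))
  center <- which.min(rowSums(dmat)) # which.min takes the first tie
  others <- setdiff(seq_along(seqs), center)
  aln <- Biostrings::pairwiseAlignment(
    pattern = ss[others], subject = ss[[center]], type = "global",
    substitutionMatrix = unit_submat(), gapOpening = 0, gapExtension = 1)
  oth_rows <- as.character(Biostrings::alignedPattern(aln))
  cen_rows <- as.character(Biostrings::alignedSubject(aln))
  lc <- nchar(seqs[center])
  # insertion profile: gaps opened in the center before each center position
  profile_of <- function(cen_aln) {
    cc <- strsplit(cen_aln, "", fixed = TRUE)[[1]]
    ins <- integer(lc + 1)
    pos <- 0L
    for (ch in cc) {
      if (ch == "-") ins[pos + 1L] <- ins[pos + 1L] + 1L else pos <- pos + 1L
    }
    ins
  }
  profiles <- lapply(cen_rows, profile_of)
  ins <- Reduce(pmax, profiles, accumulate = FALSE,
                init = integer(lc + 1))
  # rebuild one row against the merged gap profile
  build_row <- function(cen_aln, oth_aln) {
    cc <- strsplit(cen_aln, "", fixed = TRUE)[[1]]
    oc <- strsplit(oth_aln, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    for (slot in 0:lc) {
      loc <- character(0)
      while (i <= length(cc) && cc[i] == "-") {
        loc <- c(loc, oc[i])
        i <- i + 1L
      }
      out <- c(out, loc, rep("-", ins[slot + 1L] - length(loc)))
      if (slot < lc) {
        out <- c(out, oc[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }
  rows <- character(length(seqs))
  rows[center] <- build_row(seqs[center], seqs[center])
  for (k in seq_along(others)) {
    rows[others[k]] <- build_row(cen_rows[k], oth_rows[k])
  }
  structure(list(ids = ids, rows = unname(rows)), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("msa: %d sequence(s), %d column(s)\n",
              length(x$ids), nchar(x$rows[1])))
  invisible(x)
}

#' Pairwise difference matrix from a multiple alignment
#'
#' Distances are plain nucleotide differences: a column counts when the two
#' rows differ, base-vs-gap included; gap-vs-gap columns and any column where
#' either row carries `N` are skipped.
#'
#' @param msa An `msa`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
msa_distance_matrix <- function(msa) {
  n <- length(msa$ids)
  chars <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  d <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    a <- chars[i, ]
    for (j in (i + 1):n) {
      b <- chars[j, ]
      diff <- sum(a != b & a != "N" & b != "N")
      d[i, j] <- d[j, i] <- diff
    }
  }
  d
}

#' Glocal identity of a query against a reference
#'
#' The query is aligned end-to-end with free end gaps on the reference
#' (semi-global alignment, unit edit costs). Identity is the number of
#' matched positions divided by the query length; `N` matches nothing.
#'
#' @param query,ref_seq Non-empty DNA strings.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' glocal_identity("ACGT", "TTACGTTT") # 1.0
glocal_identity <- function(query, ref_seq) {
  query <- normalize_dna(query)
  ref_seq <- normalize_dna(ref_seq)
  if (!nchar(query) || !nchar(ref_seq)) stop("empty sequence", call. = FALSE)
  em <- .glocal_align_cpp(query, ref_seq)
  em[2] / nchar(query)
}
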