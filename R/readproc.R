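# ---- sample indices ---------------------------------------------------------

# minimum pairwise Hamming distance of equal-length strings
min_hamming <- function(x) {
  if (length(x) < 2) return(Inf)
  chars <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  best <- Inf
  for (i in seq_len(nrow(chars) - 1)) {
    d <- rowSums(chars[(i + 1):nrow(chars), , drop = FALSE] !=
                   matrix(chars[i, ], nrow(chars) - i, ncol(chars),
                          byrow = TRUE))
    best <- min(best, d)
  }
  best
}

#' Design a set of sample indices
#'
#' Greedy randomized construction of `n` distinct indices of the given length
#' with every pair at Hamming distance at least `min_dist`, so that a single
#' sequencing error cannot convert one index into another. Deterministic for
#' a given seed.
#'
#' @param n Number of indices.
#' @param length Index length in nucleotides (default 6).
#' @param min_dist Minimum pairwise Hamming distance (default 2).
#' @param seed RNG seed.
#' @return Character vector of `n` index sequences.
#' @export
design_index_set <- function(n, length = 6L, min_dist = 2L, seed = 1L) {
  stopifnot(n >= 1, length >= 1, min_dist >= 0)
  if (n > 1 && min_dist > length) {
    stop("infeasible: min_dist (", min_dist, ") exceeds index length (",
         length, ")", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    accepted <- matrix(character(0), 0, length)
    attempts <- 0L
    limit <- max(10000L, 1000L * n)
    while (nrow(accepted) < n) {
      if (attempts >= limit) {
        stop("index design stalled after ", attempts, " attempts: reached ",
             nrow(accepted), " of ", n, " indices (length ", length,
             ", min_dist ", min_dist, ")", call. = FALSE)
      }
      attempts <- attempts + 1L
      cand <- sample(bases, length, replace = TRUE)
      if (nrow(accepted) == 0 ||
          min(rowSums(accepted != matrix(cand, nrow(accepted), length,
                                         byrow = TRUE))) >= min_dist) {
        accepted <- rbind(accepted, cand)
      }
    }
    apply(accepted, 1, paste, collapse = "")
  })
}

#' Read or validate a sample sheet
#'
#' Maps 6-nt sample indices to sample metadata. Indices must be unique, of
#' equal length and pairwise Hamming distance >= 2 (the design constraint the
#' indices were built under).
#'
#' @param x Path to a TSV with header `index  sample_id  site  region
#'   timepoint`, or an equivalent data frame.
#' @return A validated `sample_sheet` data frame.
#' @export
sample_sheet <- function(x) {
  tab <- if (is.character(x)) {
    read.delim(x, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               colClasses = "character")
  } else as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("index", "sample_id")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("site", "region", "timepoint")) {
    if (is.null(tab[[col]])) tab[[col]] <- ""
  }
  tab$index <- normalize_dna(tab$index)
  if (anyDuplicated(tab$index)) stop("duplicate indices", call. = FALSE)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids", call. = FALSE)
  if (length(unique(nchar(tab$index))) != 1) {
    stop("indices differ in length", call. = FALSE)
  }
  if (min_hamming(tab$index) < 2) {
    stop("indices violate the pairwise Hamming distance >= 2 constraint",
         call. = FALSE)
  }
  class(tab) <- c("sample_sheet", "data.frame")
  tab
}

# ---- FASTQ I/O --------------------------------------------------------------

#' Read an indexed paired-end run from three FASTQ files
#'
#' @param r1_path,r2_path,index_path Phred+33 FASTQ files in matched read
#'   order; the index read carries the 6-nt sample index.
#' @return Data frame with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual`, `index_seq` (qualities as Phred+33 strings).
#' @export
read_fastq_run <- function(r1_path, r2_path, index_path) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq",
                                      with.qualities = TRUE)
    list(id = sub("\\s.*$", "", names(x)),
         seq = unname(as.character(x)),
         qual = unname(as.character(S4Vectors::mcols(x)$qualities)))
  }
  r1 <- rd(r1_path); r2 <- rd(r2_path); ix <- rd(index_path)
  if (length(r1$id) != length(r2$id) || length(r1$id) != length(ix$id)) {
    stop("FASTQ files differ in read count", call. = FALSE)
  }
  data.frame(id = r1$id, r1_seq = r1$seq, r1_qual = r1$qual,
             r2_seq = r2$seq, r2_qual = r2$qual, index_seq = ix$seq,
             stringsAsFactors = FALSE)
}

write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs, ids))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

# ---- demultiplexing ---------------------------------------------------------

#' Assign read pairs to samples by their index
#'
#' Under the default (and only) `"exact"` policy an index must equal a sample
#' sheet entry verbatim; anything else lands in `"unassigned"`. With indices
#' designed at pairwise distance 2 a single sequencing error could otherwise
#' be mis-corrected into a different sample.
#'
#' @param pairs Data frame from [read_fastq_run()].
#' @param sheet A [sample_sheet()].
#' @param policy Index matching policy; only `"exact"` is implemented.
#' @return Named list of data frames, one per sample plus `"unassigned"`.
#'   Row counts over the list always sum to `nrow(pairs)`.
#' @export
demultiplex <- function(pairs, sheet, policy = c("exact")) {
  policy <- match.arg(policy)
  sample <- sheet$sample_id[match(pairs$index_seq, sheet$index)]
  sample[is.na(sample)] <- "unassigned"
  out <- split(pairs, factor(sample, levels = c(sheet$sample_id,
                                                "unassigned")))
  lapply(out, function(df) { rownames(df) <- NULL; df })
}

# ---- primer identification and trimming -------------------------------------

# mismatches of `primer` against the 5' end of each read at offsets
# 0..max_offset; NA where the read is too short
prefix_mismatch_matrix <- function(reads, primer, max_offset) {
  sets <- iupac_sets()[strsplit(primer, "", fixed = TRUE)[[1]]]
  m <- length(sets)
  span <- max_offset + m
  ch <- lapply(seq_len(span), function(p) substr(reads, p, p))
  n <- length(reads)
  out <- matrix(NA_integer_, n, max_offset + 1L)
  lens <- nchar(reads)
  for (o in 0:max_offset) {
    mm <- integer(n)
    for (k in seq_len(m)) mm <- mm + !(ch[[o + k]] %in% sets[[k]])
    mm[lens < o + m] <- NA_integer_
    out[, o + 1L] <- mm
  }
  out
}

# best (min-mismatch) offset per read; ties -> smallest offset
best_prefix_hit <- function(mm_matrix) {
  n <- nrow(mm_matrix)
  filled <- mm_matrix
  filled[is.na(filled)] <- .Machine$integer.max
  best <- filled[, 1]
  off <- rep(0L, n)
  for (o in seq_len(ncol(filled) - 1)) {
    upd <- filled[, o + 1] < best
    best[upd] <- filled[upd, o + 1]
    off[upd] <- o
  }
  list(mismatches = best, offset = off)
}

# leftmost occurrence (1-based start) of an IUPAC pattern in each sequence,
# NA when absent; used for 3' read-through trimming
leftmost_hit <- function(seqs, pattern, max_mismatch) {
  starts <- rep(NA_integer_, length(seqs))
  long_enough <- which(nchar(seqs) >= nchar(pattern))
  if (!length(long_enough)) return(starts)
  subj <- Biostrings::DNAStringSet(seqs[long_enough])
  names(subj) <- as.character(seq_along(long_enough))
  m <- Biostrings::vmatchPattern(pattern, subj, max.mismatch = max_mismatch,
                                 fixed = "subject")
  hits <- unlist(m)
  if (length(hits)) {
    first <- tapply(IRanges::start(hits), names(hits), min)
    starts[long_enough[as.integer(names(first))]] <- as.integer(first)
  }
  starts
}

#' Identify the assay and trim primer sequences from read pairs
#'
#' The forward primer is searched (degenerate-aware) at the 5' end of read 1
#' at offsets 0 to `max_offset`, the reverse primer at the 5' end of read 2;
#' each site may carry at most `max_mismatch` mismatches. The assay is the
#' panel entry minimizing the total mismatch count; an exact tie between
#' assays rejects the pair as `"ambiguous"`, no qualifying assay rejects it
#' as `"no_primer"`. The primer and any preceding bases are trimmed. If the
#' reverse complement of the opposite primer occurs within an insert
#' (read-through across a short amplicon) it and everything 3' of it are
#' trimmed as well.
#'
#' @param pairs Data frame with columns `id`, `r1_seq`, `r1_qual`, `r2_seq`,
#'   `r2_qual` (one or many rows).
#' @param panel A [primer_panel()].
#' @param max_mismatch Maximum mismatches per primer site (default 2).
#' @param max_offset Maximum 5' offset at which a primer may start (default 5).
#' @return List with `trimmed` (columns `id`, `assay`, `r1_insert`,
#'   `r1_qual`, `r2_insert`, `r2_qual`, `fwd_mismatches`, `rev_mismatches`)
#'   and `rejected` (columns `id`, `reason`).
#' @export
identify_and_trim <- function(pairs, panel, max_mismatch = 2L,
                              max_offset = 5L) {
  n <- nrow(pairs)
  n_assay <- nrow(panel)
  tot <- matrix(NA_integer_, n, n_assay)
  off1 <- matrix(0L, n, n_assay)
  off2 <- matrix(0L, n, n_assay)
  mm1 <- matrix(NA_integer_, n, n_assay)
  mm2 <- matrix(NA_integer_, n, n_assay)
  for (a in seq_len(n_assay)) {
    h1 <- best_prefix_hit(prefix_mismatch_matrix(pairs$r1_seq,
                                                 panel$forward[a], max_offset))
    h2 <- best_prefix_hit(prefix_mismatch_matrix(pairs$r2_seq,
                                                 panel$reverse[a], max_offset))
    ok <- h1$mismatches <= max_mismatch & h2$mismatches <= max_mismatch
    tot[ok, a] <- h1$mismatches[ok] + h2$mismatches[ok]
    off1[, a] <- h1$offset; off2[, a] <- h2$offset
    mm1[, a] <- h1$mismatches; mm2[, a] <- h2$mismatches
  }
  filled <- tot
  filled[is.na(filled)] <- .Machine$integer.max
  best_tot <- do.call(pmin, lapply(seq_len(n_assay), function(a) filled[, a]))
  n_best <- rowSums(filled == best_tot)
  has_hit <- best_tot < .Machine$integer.max
  ambiguous <- has_hit & n_best > 1
  usable <- has_hit & !ambiguous
  assay_idx <- max.col(-filled, ties.method = "first")
  reason <- rep(NA_character_, n)
  reason[!has_hit] <- "no_primer"
  reason[ambiguous] <- "ambiguous"
  # trim the usable reads, grouped by winning assay
  trimmed <- NULL
  if (any(usable)) {
    rows <- list()
    for (a in unique(assay_idx[usable])) {
      sel <- which(usable & assay_idx == a)
      flen <- nchar(panel$forward[a]); rlen <- nchar(panel$reverse[a])
      s1 <- off1[sel, a] + flen + 1L
      s2 <- off2[sel, a] + rlen + 1L
      r1 <- substring(pairs$r1_seq[sel], s1)
      q1 <- substring(pairs$r1_qual[sel], s1)
      r2 <- substring(pairs$r2_seq[sel], s2)
      q2 <- substring(pairs$r2_qual[sel], s2)
      # 3' read-through: opposite primer, reverse-complemented
      rt1 <- leftmost_hit(r1, revcomp(panel$reverse[a]), max_mismatch)
      cut <- !is.na(rt1)
      r1[cut] <- substr(r1[cut], 1, rt1[cut] - 1L)
      q1[cut] <- substr(q1[cut], 1, rt1[cut] - 1L)
      rt2 <- leftmost_hit(r2, revcomp(panel$forward[a]), max_mismatch)
      cut <- !is.na(rt2)
      r2[cut] <- substr(r2[cut], 1, rt2[cut] - 1L)
      q2[cut] <- substr(q2[cut], 1, rt2[cut] - 1L)
      rows[[length(rows) + 1]] <- data.frame(
        row = sel, id = pairs$id[sel], assay = panel$assay[a],
        r1_insert = r1, r1_qual = q1, r2_insert = r2, r2_qual = q2,
        fwd_mismatches = mm1[sel, a], rev_mismatches = mm2[sel, a],
        stringsAsFactors = FALSE)
    }
    trimmed <- do.call(rbind, rows)
    trimmed <- trimmed[order(trimmed$row), , drop = FALSE]
    empty <- nchar(trimmed$r1_insert) == 0 | nchar(trimmed$r2_insert) == 0
    reason[trimmed$row[empty]] <- "empty_insert"
    trimmed <- trimmed[!empty, setdiff(names(trimmed), "row"), drop = FALSE]
    rownames(trimmed) <- NULL
  }
  if (is.null(trimmed)) {
    trimmed <- data.frame(id = character(0), assay = character(0),
                          r1_insert = character(0), r1_qual = character(0),
                          r2_insert = character(0), r2_qual = character(0),
                          fwd_mismatches = integer(0),
                          rev_mismatches = integer(0))
  }
  rejected <- data.frame(id = pairs$id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  list(trimmed = trimmed, rejected = rejected)
}

# ---- length filters ---------------------------------------------------------

#' Length filters on trimmed read pairs
#'
#' Rejects a pair when either insert is shorter than the assay's minimum
#' (`min_read_len` in the panel; 50 bp unless an assay targeting short
#' amplicons overrides it), or when the two inserts differ in length by more
#' than `max_len_diff` (a symptom of a primer found in only one mate).
#'
#' @param trimmed `trimmed` data frame from [identify_and_trim()].
#' @param panel A [primer_panel()].
#' @param max_len_diff Maximum tolerated per-mate length difference
#'   (default 5 bp).
#' @return List with `pass` (surviving rows) and `rejected` (`id`, `reason`).
#' @export
length_filters <- function(trimmed, panel, max_len_diff = 5L) {
  min_len <- panel$min_read_len[match(trimmed$assay, panel$assay)]
  l1 <- nchar(trimmed$r1_insert)
  l2 <- nchar(trimmed$r2_insert)
  too_short <- l1 < min_len | l2 < min_len
  len_mismatch <- !too_short & abs(l1 - l2) > max_len_diff
  reason <- ifelse(too_short, "too_short",
                   ifelse(len_mismatch, "length_mismatch", NA_character_))
  keep <- is.na(reason)
  pass <- trimmed[keep, , drop = FALSE]
  rownames(pass) <- NULL
  list(pass = pass,
       rejected = data.frame(id = trimmed$id[!keep],
                             reason = reason[!keep]))
}

# ---- pair merging -----------------------------------------------------------

#' Merge trimmed read pairs into consensus sequences
#'
#' Read 2 is reverse-complemented and slid along read 1; the offset
#' maximizing the overlap score (+1 match / -1 mismatch) is chosen among
#' offsets with overlap of at least `min_overlap` bases and overlap identity
#' of at least `min_overlap_identity`. Where the mates agree the base is
#' kept; disagreements resolve to the base with the higher Phred quality
#' (ties keep the read-1 base). The consensus spans the union of the two
#' reads.
#'
#' @param trimmed `trimmed` (or `pass`) data frame rows.
#' @param min_overlap Minimum overlap length (default 10).
#' @param min_overlap_identity Minimum fraction of matching overlap positions
#'   (default 0.8).
#' @return Character vector of consensus sequences, `NA` where no admissible
#'   overlap exists (rejection reason `"no_overlap"`).
#' @export
merge_pair <- function(trimmed, min_overlap = 10L, min_overlap_identity = 0.8) {
  if (nrow(trimmed) == 0) return(character(0))
  b <- revcomp(trimmed$r2_insert)
  qb <- as.character(Biostrings::reverse(Biostrings::BStringSet(trimmed$r2_qual)))
  .merge_overlap_many_cpp(trimmed$r1_insert, trimmed$r1_qual, b, qb,
                          as.integer(min_overlap), min_overlap_identity)
}

# ---- dereplication ----------------------------------------------------------

#' Dereplicate consensus sequences into unique sequences with counts
#'
#' Collapses identical `(assay, sequence)` strings and counts how many reads
#' carry each unique sequence in each sample. Counts always sum to the input
#' row count, and the result does not depend on input order.
#'
#' @param consensus Data frame with columns `sample_id`, `assay`, `seq`.
#' @return A `derep_set`: list with `seqs` (data frame `seq_id`, `assay`,
#'   `sequence`, `total_reads`) and `counts` (integer matrix unique sequence
#'   x sample).
#' @export
dereplicate <- function(consensus) {
  stopifnot(all(c("sample_id", "assay", "seq") %in% names(consensus)))
  if (nrow(consensus) == 0) {
    return(structure(list(
      seqs = data.frame(seq_id = character(0), assay = character(0),
                        sequence = character(0), total_reads = integer(0)),
      counts = matrix(0L, 0, 0)), class = "derep_set"))
  }
  key <- paste(consensus$assay, consensus$seq, sep = "\r")
  counts <- table(key, consensus$sample_id)
  counts <- matrix(as.integer(counts), nrow(counts), ncol(counts),
                   dimnames = dimnames(counts))
  parts <- strsplit(rownames(counts), "\r", fixed = TRUE)
  seqs <- data.frame(assay = vapply(parts, `[`, character(1), 1),
                     sequence = vapply(parts, `[`, character(1), 2),
                     total_reads = as.integer(rowSums(counts)))
  ord <- order(seqs$assay, -seqs$total_reads, seqs$sequence)
  seqs <- seqs[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  seqs$seq_id <- sprintf("%s_u%05d", seqs$assay,
                         stats::ave(seq_len(nrow(seqs)), seqs$assay,
                                    FUN = seq_along))
  rownames(counts) <- seqs$seq_id
  seqs <- seqs[, c("seq_id", "assay", "sequence", "total_reads")]
  rownames(seqs) <- NULL
  structure(list(seqs = seqs, counts = counts), class = "derep_set")
}

#' @export
print.derep_set <- function(x, ...) {
  cat(sprintf("derep_set: %d unique sequence(s), %d sample(s), %d read(s)\n",
              nrow(x$seqs), ncol(x$counts), sum(x$seqs$total_reads)))
  invisible(x)
}

# ---- pipeline driver --------------------------------------------------------

#' Run the full read-processing pipeline
#'
#' Demultiplex -> identify/trim primers -> length filters -> merge pairs ->
#' dereplicate, with a per-stage rejection tally. Reads are conserved:
#' `unassigned + rejections + merged == input`.
#'
#' @param pairs Data frame from [read_fastq_run()].
#' @param sheet A [sample_sheet()].
#' @param panel A [primer_panel()].
#' @param max_mismatch,max_offset Passed to [identify_and_trim()].
#' @param min_overlap,min_overlap_identity Passed to [merge_pair()].
#' @param max_len_diff Passed to [length_filters()].
#' @return List with `derep` (a `derep_set`), `consensus` (long data frame
#'   `sample_id`, `assay`, `seq`) and `log` (data frame `stage`, `reason`,
#'   `n`).
#' @export
run_read_pipeline <- function(pairs, sheet, panel, max_mismatch = 2L,
                              max_offset = 5L, min_overlap = 10L,
                              min_overlap_identity = 0.8, max_len_diff = 5L) {
  demux <- demultiplex(pairs, sheet)
  unassigned <- nrow(demux$unassigned)
  assigned <- do.call(rbind, lapply(sheet$sample_id, function(s) {
    df <- demux[[s]]
    df$sample_id <- rep(s, nrow(df))
    df
  }))
  log <- data.frame(stage = "demultiplex", reason = "unassigned",
                    n = unassigned)
  if (is.null(assigned) || nrow(assigned) == 0) {
    return(list(derep = dereplicate(data.frame(sample_id = character(0),
                                               assay = character(0),
                                               seq = character(0))),
                consensus = NULL, log = log))
  }
  tr <- identify_and_trim(assigned, panel, max_mismatch, max_offset)
  sample_of <- setNames(assigned$sample_id, assigned$id)
  if (nrow(tr$rejected)) {
    tal <- table(tr$rejected$reason)
    log <- rbind(log, data.frame(stage = "trim", reason = names(tal),
                                 n = as.integer(tal)))
  }
  lf <- length_filters(tr$trimmed, panel, max_len_diff)
  if (nrow(lf$rejected)) {
    tal <- table(lf$rejected$reason)
    log <- rbind(log, data.frame(stage = "length_filter", reason = names(tal),
                                 n = as.integer(tal)))
  }
  cons <- merge_pair(lf$pass, min_overlap, min_overlap_identity)
  merged <- !is.na(cons)
  if (any(!merged)) {
    log <- rbind(log, data.frame(stage = "merge", reason = "no_overlap",
                                 n = sum(!merged)))
  }
  consensus <- data.frame(sample_id = unname(sample_of[lf$pass$id[merged]]),
                          assay = lf$pass$assay[merged],
                          seq = cons[merged], stringsAsFactors = FALSE)
  log <- rbind(log, data.frame(stage = "merge", reason = "merged",
                               n = nrow(consensus)))
  list(derep = dereplicate(consensus), consensus = consensus, log = log)
}
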