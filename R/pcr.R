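#' In-silico PCR configuration
#'
#' @param max_mismatch_per_primer Maximum mismatches tolerated per primer
#'   binding site (default 2).
#' @param three_prime_exact Number of 3'-terminal primer bases that must match
#'   exactly (default 2); mismatches there abolish extension.
#' @param permutation_cap Maximum number of concrete primer permutations
#'   sampled from a degenerate primer (default 25).
#' @param amplicon_cap Maximum number of amplicons returned per prediction;
#'   larger result sets are down-sampled uniformly (default 500).
#' @param seed Seed for the sampling steps.
#' @return A list of class `pcr_config`.
#' @export
pcr_config <- function(max_mismatch_per_primer = 2L, three_prime_exact = 2L,
                       permutation_cap = 25L, amplicon_cap = 500L, seed = 1L) {
  stopifnot(max_mismatch_per_primer >= 0, three_prime_exact >= 0,
            permutation_cap >= 1, amplicon_cap >= 1)
  structure(list(max_mismatch_per_primer = as.integer(max_mismatch_per_primer),
                 three_prime_exact = as.integer(three_prime_exact),
                 permutation_cap = as.integer(permutation_cap),
                 amplicon_cap = as.integer(amplicon_cap),
                 seed = as.integer(seed)),
            class = "pcr_config")
}

# Validate and normalize a primer sequence (full IUPAC alphabet, >= 10 nt).
validate_primer <- function(seq, what = "primer") {
  seq <- normalize_dna(seq)
  check_alphabet(seq, iupac_alphabet(), what = what)
  if (any(nchar(seq) < 10)) {
    stop(what, " shorter than 10 nt: ", paste(seq[nchar(seq) < 10],
                                              collapse = ", "), call. = FALSE)
  }
  seq
}

#' Read a primer panel definition
#'
#' Tab-separated with header:
#' `assay  forward  reverse  min_product  max_product  min_read_len`.
#' `min_product`/`max_product` bound the predicted product length (primers
#' included); `min_read_len` is the per-assay minimum trimmed insert length
#' used by [length_filters()] (assays targeting very short amplicons, e.g.
#' plant/bryophyte trnL, set it below the 50 bp default).
#'
#' @param path Path to the panel TSV.
#' @return A data frame of class `primer_panel`.
#' @export
read_primer_panel <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  primer_panel(tab)
}

#' Construct/validate a primer panel
#'
#' @param tab Data frame with columns `assay`, `forward`, `reverse` and
#'   optionally `min_product` (default 50), `max_product` (default 3000) and
#'   `min_read_len` (default 50).
#' @return The validated panel (class `primer_panel`).
#' @export
primer_panel <- function(tab) {
  need <- c("assay", "forward", "reverse")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("primer panel is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$assay)) stop("duplicate assay names", call. = FALSE)
  if (is.null(tab$min_product)) tab$min_product <- 50L
  if (is.null(tab$max_product)) tab$max_product <- 3000L
  if (is.null(tab$min_read_len)) tab$min_read_len <- 50L
  tab$forward <- validate_primer(tab$forward, "forward primer")
  tab$reverse <- validate_primer(tab$reverse, "reverse primer")
  stopifnot(all(tab$min_product > 0),
            all(tab$min_product <= tab$max_product))
  class(tab) <- c("primer_panel", "data.frame")
  tab
}

#' Expand a degenerate primer into concrete sequences
#'
#' A primer with IUPAC ambiguity codes stands for the set of all concrete
#' sequences obtained by substituting each degenerate position with one base
#' from its set; each degenerate position multiplies the number of concrete
#' primers (up to four-fold). If that number is at most `cap` all expansions
#' are returned in lexicographic order, otherwise `cap` distinct permutations
#' are sampled uniformly without replacement.
#'
#' @param primer IUPAC DNA string.
#' @param cap Maximum number of permutations returned (default 25).
#' @param seed Seed used when sampling is required.
#' @return Character vector of concrete primer sequences.
#' @export
#' @examples
#' expand_degenerate("ACGTACGTNR")
expand_degenerate <- function(primer, cap = 25L, seed = 1L) {
  if (cap < 1) stop("cap must be >= 1", call. = FALSE)
  primer <- normalize_dna(primer)
  check_alphabet(primer, iupac_alphabet(), what = "primer")
  sets <- iupac_sets()[strsplit(primer, "")[[1]]]
  total <- prod(vapply(sets, length, integer(1)))
  if (total <= cap) {
    out <- Reduce(function(acc, s) {
      as.vector(vapply(acc, function(a) paste0(a, s),
                       character(length(s))))
    }, sets, accumulate = FALSE, init = "")
    return(sort(out))
  }
  # uniform without replacement over the product space by rejection
  withr::with_seed(seed, {
    picked <- character(0)
    while (length(picked) < cap) {
      cand <- paste(vapply(sets, function(s) s[sample.int(length(s), 1)],
                           character(1)), collapse = "")
      if (!cand %in% picked) picked <- c(picked, cand)
    }
    picked
  })
}

# Mismatch profile of a concrete-or-degenerate pattern along a reference.
# Returns, for every 0-based offset, the total mismatch count and the
# mismatch count restricted to `tail_positions` of the pattern. A reference
# base outside the pattern position's IUPAC set is a mismatch; reference 'N'
# (or any ambiguity code) never satisfies a primer position.
slide_mismatches <- function(ref_chars, pattern, tail_positions) {
  sets <- iupac_sets()
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc)
  n_off <- length(ref_chars) - m + 1
  if (n_off < 1) {
    return(list(mismatches = integer(0), tail = integer(0)))
  }
  mism <- integer(n_off)
  tail_mism <- integer(n_off)
  for (k in seq_len(m)) {
    bad <- !(ref_chars[k:(k + n_off - 1)] %in% sets[[pc[k]]])
    mism <- mism + bad
    if (k %in% tail_positions) tail_mism <- tail_mism + bad
  }
  list(mismatches = mism, tail = tail_mism)
}

#' Locate primer binding sites on a reference sequence
#'
#' Scans both strands. A position is a hit iff the total number of mismatches
#' is at most `config$max_mismatch_per_primer` **and** the final
#' `config$three_prime_exact` 3' bases of the primer match exactly.
#' Degenerate primer positions match any base in their IUPAC set at zero
#' cost; a reference `N` never matches.
#'
#' @param ref_seq Reference DNA string (plus strand).
#' @param primer IUPAC primer string.
#' @param config A [pcr_config()].
#' @return Data frame with columns `strand` (`+`/`-`), `start`, `end`
#'   (0-based half-open on the plus strand) and `mismatches`.
#' @export
match_primer <- function(ref_seq, primer, config = pcr_config()) {
  primer <- normalize_dna(primer)
  check_alphabet(primer, iupac_alphabet(), what = "primer")
  ref_seq <- normalize_dna(ref_seq)
  rc_chars <- strsplit(ref_seq, "")[[1]]
  m <- nchar(primer)
  t3 <- min(config$three_prime_exact, m)
  hits <- list()
  # plus strand: primer as-is, 3' end = last t3 pattern positions
  tail_plus <- if (t3 > 0) (m - t3 + 1):m else integer(0)
  p <- slide_mismatches(rc_chars, primer, tail_positions = tail_plus)
  keep <- which(p$mismatches <= config$max_mismatch_per_primer & p$tail == 0)
  if (length(keep)) {
    hits[["+"]] <- data.frame(strand = "+", start = keep - 1L,
                              end = keep - 1L + m,
                              mismatches = p$mismatches[keep])
  }
  # minus strand: reverse complement of the primer on the plus strand;
  # the primer's 3' end maps to the *first* t3 pattern positions
  q <- slide_mismatches(rc_chars, revcomp(primer), tail_positions = seq_len(t3))
  keep <- which(q$mismatches <= config$max_mismatch_per_primer & q$tail == 0)
  if (length(keep)) {
    hits[["-"]] <- data.frame(strand = "-", start = keep - 1L,
                              end = keep - 1L + m,
                              mismatches = q$mismatches[keep])
  }
  if (!length(hits)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  }
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Predict amplicons of a primer pair against a reference database
#'
#' For every reference sequence, each combination of a forward-primer hit and
#' a reverse-primer hit on opposite strands in amplifiable (inward-facing)
#' orientation with a product length within the pair's bounds yields one
#' amplicon. The insert is the sequence strictly between the two primer
#' binding sites, reported 5'->3' from the forward primer. If more than
#' `config$amplicon_cap` amplicons are found, that many are sampled uniformly
#' without replacement using `config$seed`.
#'
#' @param db A `reference_db`.
#' @param pair One row of a [primer_panel()] (or a list with fields `assay`,
#'   `forward`, `reverse`, `min_product`, `max_product`).
#' @param config A [pcr_config()].
#' @return An `amplicon_set` data frame: `ref_id`, `assay`, `strand`,
#'   `product_start`, `product_end` (0-based half-open, primers included),
#'   `insert_seq`, `fwd_mismatches`, `rev_mismatches`, plus the seven lineage
#'   columns copied from the reference.
#' @export
predict_amplicons <- function(db, pair, config = pcr_config()) {
  if (nrow(db) == 0) stop("empty reference database", call. = FALSE)
  fwd <- validate_primer(pair$forward, "forward primer")
  rev <- validate_primer(pair$reverse, "reverse primer")
  res <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    ref <- db$seq[i]
    fh <- match_primer(ref, fwd, config)
    if (!nrow(fh)) next
    rh <- match_primer(ref, rev, config)
    if (!nrow(rh)) next
    amps <- list()
    # forward on +, reverse on - , reverse site downstream
    fp <- fh[fh$strand == "+", , drop = FALSE]
    rm_ <- rh[rh$strand == "-", , drop = FALSE]
    for (a in seq_len(nrow(fp))) for (b in seq_len(nrow(rm_))) {
      if (rm_$start[b] >= fp$end[a]) {
        len <- rm_$end[b] - fp$start[a]
        if (len >= pair$min_product && len <= pair$max_product) {
          amps[[length(amps) + 1]] <- data.frame(
            ref_id = db$id[i], strand = "+",
            product_start = fp$start[a], product_end = rm_$end[b],
            insert_seq = substr(ref, fp$end[a] + 1, rm_$start[b]),
            fwd_mismatches = fp$mismatches[a], rev_mismatches = rm_$mismatches[b])
        }
      }
    }
    # forward on -, reverse on +, forward site downstream (product on -)
    fm <- fh[fh$strand == "-", , drop = FALSE]
    rp <- rh[rh$strand == "+", , drop = FALSE]
    for (a in seq_len(nrow(fm))) for (b in seq_len(nrow(rp))) {
      if (fm$start[a] >= rp$end[b]) {
        len <- fm$end[a] - rp$start[b]
        if (len >= pair$min_product && len <= pair$max_product) {
          amps[[length(amps) + 1]] <- data.frame(
            ref_id = db$id[i], strand = "-",
            product_start = rp$start[b], product_end = fm$end[a],
            insert_seq = revcomp(substr(ref, rp$end[b] + 1, fm$start[a])),
            fwd_mismatches = fm$mismatches[a], rev_mismatches = rp$mismatches[b])
        }
      }
    }
    if (length(amps)) res[[i]] <- do.call(rbind, amps)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    message("predict_amplicons: no amplicons for assay '", pair$assay, "'")
    out <- data.frame(ref_id = character(0), strand = character(0),
                      product_start = integer(0), product_end = integer(0),
                      insert_seq = character(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0))
  }
  if (nrow(out) > config$amplicon_cap) {
    keep <- withr::with_seed(config$seed,
                             sample.int(nrow(out), config$amplicon_cap))
    out <- out[sort(keep), , drop = FALSE]
  }
  out$assay <- if (nrow(out)) pair$assay else character(0)
  lin <- db[match(out$ref_id, db$id), rank_ladder(), drop = FALSE]
  out <- cbind(out[, c("ref_id", "assay", "strand", "product_start",
                       "product_end", "insert_seq", "fwd_mismatches",
                       "rev_mismatches")], lin)
  rownames(out) <- NULL
  class(out) <- c("amplicon_set", "data.frame")
  out
}

#' Summarize an amplicon prediction
#'
#' Reports, per taxonomic rank, the number of distinct taxa amplified and the
#' number of amplicons per taxon, plus insert-length statistics.
#'
#' @param amplicons An `amplicon_set`.
#' @return A list of class `pcr_summary` with elements `n_amplicons`,
#'   `insert_length` (named `min`/`mean`/`max`), `taxa_counts` (named integer
#'   vector per rank) and `amplicons_per_taxon` (list of per-rank tables).
#' @export
pcr_summary <- function(amplicons) {
  lens <- nchar(amplicons$insert_seq)
  taxa_counts <- vapply(rank_ladder(), function(r) {
    length(setdiff(unique(amplicons[[r]]), ""))
  }, integer(1))
  per_taxon <- lapply(setNames(rank_ladder(), rank_ladder()), function(r) {
    tx <- amplicons[[r]][amplicons[[r]] != ""]
    if (!length(tx)) return(table(character(0)))
    table(tx)
  })
  structure(list(
    n_amplicons = nrow(amplicons),
    insert_length = if (length(lens)) {
      c(min = min(lens), mean = mean(lens), max = max(lens))
    } else c(min = 0, mean = 0, max = 0),
    taxa_counts = taxa_counts,
    amplicons_per_taxon = per_taxon), class = "pcr_summary")
}

#' @export
print.pcr_summary <- function(x, ...) {
  cat(sprintf("in-silico PCR summary: %d amplicon(s)\n", x$n_amplicons))
  cat(sprintf("  insert length: min %g / mean %.1f / max %g bp\n",
              x$insert_length["min"], x$insert_length["mean"],
              x$insert_length["max"]))
  cat("  distinct taxa amplified:\n")
  for (r in names(x$taxa_counts)) {
    cat(sprintf("    %-13s %d\n", r, x$taxa_counts[[r]]))
  }
  invisible(x)
}

#' Write predicted amplicons to FASTA
#'
#' Lineage is carried in the header as `rank=taxon` tokens so downstream
#' tools keep the annotation.
#'
#' @param amplicons An `amplicon_set`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_amplicons <- function(amplicons, path) {
  hdr <- vapply(seq_len(nrow(amplicons)), function(i) {
    lin <- paste0(rank_ladder(), "=", unlist(amplicons[i, rank_ladder()]),
                  collapse = ";")
    sprintf("%s|%s|%d %s", amplicons$ref_id[i], amplicons$assay[i], i, lin)
  }, character(1))
  ss <- Biostrings::DNAStringSet(setNames(amplicons$insert_seq, hdr))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
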