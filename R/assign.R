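#' Remove unique sequences supported by too few reads
#'
#' Unique sequences observed in fewer than `min_total` reads summed across
#' all samples are treated as likely sequencing/PCR errors and removed before
#' taxonomic assignment.
#'
#' @param derep A `derep_set` from [dereplicate()].
#' @param min_total Minimum total read count to keep a sequence (default 10).
#' @return List with `kept` and `removed` (both `derep_set`s),
#'   `removed_seq_fraction` and `removed_read_fraction`.
#' @export
filter_low_count <- function(derep, min_total = 10L) {
  keep <- derep$seqs$total_reads >= min_total
  subset_derep <- function(sel) {
    structure(list(seqs = {
      df <- derep$seqs[sel, , drop = FALSE]; rownames(df) <- NULL; df
    }, counts = derep$counts[sel, , drop = FALSE]), class = "derep_set")
  }
  total_reads <- sum(derep$seqs$total_reads)
  list(kept = subset_derep(keep), removed = subset_derep(!keep),
       removed_seq_fraction = if (length(keep)) mean(!keep) else 0,
       removed_read_fraction = if (total_reads > 0) {
         sum(derep$seqs$total_reads[!keep]) / total_reads
       } else 0)
}

#' Assign species to unique sequences by best-hit identity
#'
#' Every sequence is compared to every reference by glocal identity
#' ([glocal_identity()]: query end-to-end, free end gaps on the reference).
#' A sequence is assigned when its best identity strictly exceeds
#' `identity_threshold`; the species set contains the species of *all*
#' references attaining the maximum (multi-species ties are kept, matching
#' the convention that a read matching several species equally is assigned
#' all of their names).
#'
#' @param derep A `derep_set` (typically the `kept` part of
#'   [filter_low_count()]).
#' @param db A `reference_db`.
#' @param identity_threshold Strict lower bound on best identity
#'   (default 0.90).
#' @return Data frame of class `assignment_set`: `seq_id`, `sequence`,
#'   `best_identity`, `status` (`assigned`/`unassigned`) and `species`
#'   (list column of tied best species names).
#' @export
assign_best_hit <- function(derep, db, identity_threshold = 0.90) {
  if (nrow(db) == 0) stop("empty reference database", call. = FALSE)
  seqs <- derep$seqs
  n <- nrow(seqs)
  best_id <- numeric(n)
  species <- vector("list", n)
  refs <- normalize_dna(db$seq)
  for (i in seq_len(n)) {
    q <- normalize_dna(seqs$sequence[i])
    matches <- .glocal_matches_cpp(q, refs)
    ident <- matches / nchar(q)
    best <- max(ident)
    best_id[i] <- best
    hit <- which(ident == best)
    species[[i]] <- sort(setdiff(unique(db$species[hit]), ""))
  }
  assigned <- best_id > identity_threshold &
    vapply(species, length, integer(1)) > 0
  out <- data.frame(seq_id = seqs$seq_id, sequence = seqs$sequence,
                    best_identity = best_id,
                    status = ifelse(assigned, "assigned", "unassigned"))
  out$species <- species
  out$species[!assigned] <- list(character(0))
  class(out) <- c("assignment_set", "data.frame")
  out
}

#' Per-sample species presence/absence matrix
#'
#' Read counts are summed per sample and species over all assigned unique
#' sequences whose species set contains that species (a sequence tied
#' between several species contributes its counts to each of them — a
#' deliberate, documented over-count). A species is called present in a
#' sample when its summed count reaches `min_reads_per_sample`.
#'
#' @param assignments An `assignment_set`.
#' @param derep The matching `derep_set` (same `seq_id`s).
#' @param sheet Optional [sample_sheet()] supplying sample metadata; samples
#'   on the sheet with no reads appear as all-absent rows.
#' @param min_reads_per_sample Presence threshold (default 10 reads).
#' @return A `presence_matrix`: list with `counts` (samples x species integer
#'   matrix), `presence` (logical matrix), `min_reads_per_sample` and
#'   `metadata` (per-sample data frame, if a sheet was given).
#' @export
presence_matrix <- function(assignments, derep, sheet = NULL,
                            min_reads_per_sample = 10L) {
  samples <- colnames(derep$counts)
  if (!is.null(sheet)) samples <- union(sheet$sample_id, samples)
  species <- sort(unique(unlist(assignments$species)))
  counts <- matrix(0L, length(samples), length(species),
                   dimnames = list(samples, species))
  keep <- assignments$status == "assigned"
  for (i in which(keep)) {
    row <- match(assignments$seq_id[i], rownames(derep$counts))
    if (is.na(row)) next
    for (sp in assignments$species[[i]]) {
      counts[colnames(derep$counts), sp] <-
        counts[colnames(derep$counts), sp] + derep$counts[row, ]
    }
  }
  metadata <- NULL
  if (!is.null(sheet)) {
    metadata <- as.data.frame(sheet)[match(samples, sheet$sample_id),
                                     c("sample_id", "site", "region",
                                       "timepoint")]
    rownames(metadata) <- NULL
  }
  structure(list(counts = counts,
                 presence = counts >= min_reads_per_sample,
                 min_reads_per_sample = as.integer(min_reads_per_sample),
                 metadata = metadata),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d sample(s) x %d species, threshold %d reads\n",
              nrow(x$counts), ncol(x$counts), x$min_reads_per_sample))
  cat(sprintf("  %d presence call(s)\n", sum(x$presence)))
  invisible(x)
}

#' Expected read count of a template at a given abundance
#'
#' At sequencing depth `mean_depth` reads, a template making up fraction
#' `abundance` of the amplifiable DNA is expected in
#' `round(abundance * mean_depth)` reads; e.g. a species at 1% of a sample
#' averaging 14,211 reads is expected in 142 reads — comfortably above a
#' 10-read detection threshold.
#'
#' @param abundance Fraction in `[0, 1]`.
#' @param mean_depth Mean reads per sample for the assay.
#' @return Integer expected read count.
#' @export
#' @examples
#' expected_read_count(0.01, 14211)
expected_read_count <- function(abundance, mean_depth) {
  stopifnot(abundance >= 0, abundance <= 1, mean_depth >= 0)
  as.integer(round(abundance * mean_depth))
}

#' Exact association test between species presence and a sample grouping
#'
#' Builds the 2 x k contingency table of presence/absence against a grouping
#' variable (e.g. river region or collection timepoint, k in 2..3) and
#' computes Fisher's exact two-sided p-value. If any table margin is zero
#' (species present everywhere or nowhere, or a group absent) the test is
#' uninformative and p = 1 is returned with a warning.
#'
#' @param present Logical vector: presence call per sample (one species).
#' @param group Factor/character vector of the same length.
#' @return Two-sided exact p-value in `(0, 1]`.
#' @export
fisher_association <- function(present, group) {
  stopifnot(length(present) == length(group))
  tab <- table(factor(present, levels = c(FALSE, TRUE)), group)
  if (ncol(tab) < 2) {
    warning("fewer than 2 groups; returning p = 1")
    return(1)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin in contingency table; returning p = 1")
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Association tests for every species in a presence matrix
#'
#' @param pm A `presence_matrix` with metadata.
#' @param grouping Metadata column to test against (`"region"` or
#'   `"timepoint"`).
#' @return Data frame `species`, `n_present`, `p_value` (raw, unadjusted).
#' @export
association_tests <- function(pm, grouping = c("region", "timepoint")) {
  grouping <- match.arg(grouping)
  if (is.null(pm$metadata)) stop("presence matrix has no metadata",
                                 call. = FALSE)
  group <- pm$metadata[[grouping]]
  usable <- !is.na(group) & group != ""
  out <- lapply(colnames(pm$presence), function(sp) {
    p <- suppressWarnings(
      fisher_association(pm$presence[usable, sp], group[usable]))
    data.frame(species = sp, n_present = sum(pm$presence[usable, sp]),
               p_value = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
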