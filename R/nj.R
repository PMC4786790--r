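#' Neighbor-Joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in the
#' minimal Q are broken by the lexicographically smallest pair of positions
#' in the current matrix (which follows the input id order). Negative
#' estimated branch lengths are clamped to zero. The result is the usual
#' unrooted tree with a basal trifurcation.
#'
#' @param dm Symmetric numeric matrix with dimnames (>= 3 ids), distances in
#'   nucleotide differences (any non-negative units work).
#' @return An [ape::read.tree()] `phylo` object with tip labels = matrix ids.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("Neighbor-Joining needs at least 3 ids", call. = FALSE)
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  if (!isTRUE(all.equal(dm, t(dm)))) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  frag <- ids # Newick fragment per active node
  D <- dm
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    mv <- min(Q)
    cand <- which(Q == mv & upper.tri(Q), arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], "joined")
    D <- D2
    frag <- c(frag[keep], new_frag)
  }
  d12 <- D[1, 2]; d13 <- D[1, 3]; d23 <- D[2, 3]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(b1), frag[2], fmt(b2), frag[3], fmt(b3))
  ape::read.tree(text = nwk)
}

#' Annotate tree tips with a taxon and export Newick + annotation table
#'
#' Each tip is labeled with the taxon its lineage carries at `rank`; unknown
#' (empty) taxa become `"unclassified"`. Color indices are assigned stably:
#' taxa are sorted alphabetically and indices cycle through a palette.
#'
#' @param tree A `phylo` object whose tip labels are sequence/amplicon ids.
#' @param lineages Data frame with an `id` column and the seven rank columns
#'   (a `reference_db` works; for amplicon trees pass the `amplicon_set` with
#'   ids matching the tips via its `ref_id`-derived labels).
#' @param rank One of [rank_ladder()].
#' @param newick_path,table_path Optional output file paths.
#' @param palette_size Number of distinct colors before indices recycle.
#' @return List with `newick` (string) and `annotation` (data frame
#'   `tip_id`, `taxon`, `color_index`).
#' @export
annotate_and_write <- function(tree, lineages, rank, newick_path = NULL,
                               table_path = NULL, palette_size = 12L) {
  rank <- match.arg(rank, rank_ladder())
  if (!"id" %in% names(lineages)) {
    stop("lineages must carry an 'id' column", call. = FALSE)
  }
  idx <- match(tree$tip.label, lineages$id)
  if (anyNA(idx)) {
    stop("no lineage for tip(s): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  taxon <- lineages[[rank]][idx]
  taxon[is.na(taxon) | taxon == ""] <- "unclassified"
  taxa <- sort(unique(taxon))
  color_of <- setNames(((seq_along(taxa) - 1L) %% palette_size) + 1L, taxa)
  ann <- data.frame(tip_id = tree$tip.label, taxon = taxon,
                    color_index = unname(color_of[taxon]))
  nwk <- ape::write.tree(tree)
  if (!is.null(newick_path)) writeLines(nwk, newick_path)
  if (!is.null(table_path)) {
    write.table(ann, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(newick = nwk, annotation = ann)
}

# Stable per-amplicon tip ids.
amplicon_ids <- function(amplicons) {
  sprintf("%s|%s|%d", amplicons$ref_id, amplicons$assay,
          seq_len(nrow(amplicons)))
}

#' Full primer evaluation: amplicons -> alignment -> annotated NJ tree
#'
#' Convenience driver chaining [predict_amplicons()], [center_star_align()],
#' [msa_distance_matrix()], [nj_tree()] and [annotate_and_write()].
#'
#' @param db A `reference_db`.
#' @param pair One primer-panel row.
#' @param rank Rank used for tip annotation (default `"class"`).
#' @param config A [pcr_config()].
#' @return List of class `primer_tree` with `amplicons`, `msa`, `dist`,
#'   `tree`, `annotation`, `newick` and `summary`.
#' @export
primer_tree <- function(db, pair, rank = "class", config = pcr_config()) {
  amps <- predict_amplicons(db, pair, config)
  if (nrow(amps) < 3) {
    stop("need at least 3 amplicons for a tree; got ", nrow(amps),
         call. = FALSE)
  }
  ids <- amplicon_ids(amps)
  msa <- center_star_align(setNames(amps$insert_seq, ids))
  dm <- msa_distance_matrix(msa)
  tree <- nj_tree(dm)
  lin <- cbind(data.frame(id = ids), amps[, rank_ladder()])
  ann <- annotate_and_write(tree, lin, rank)
  structure(list(amplicons = amps, msa = msa, dist = dm, tree = tree,
                 annotation = ann$annotation, newick = ann$newick,
                 summary = pcr_summary(amps)),
            class = "primer_tree")
}

#' @export
print.primer_tree <- function(x, ...) {
  cat("primer_tree analysis\n")
  print(x$summary)
  cat(sprintf("  tree: %d tips, %d taxa at annotation rank\n",
              length(x$tree$tip.label), length(unique(x$annotation$taxon))))
  invisible(x)
}

#' Minimal static rendering of an annotated primer tree
#'
#' @param x A `primer_tree`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, `x`.
#' @method plot primer_tree
#' @export
plot.primer_tree <- function(x, ...) {
  cols <- grDevices::hcl.colors(max(x$annotation$color_index), "Dark 3")
  ape::plot.phylo(x$tree, tip.color = cols[x$annotation$color_index],
                  cex = 0.6, no.margin = TRUE, ...)
  invisible(x)
}

#' Per-rank resolution metrics for a set of amplicons
#'
#' For each taxonomic rank reports the number of distinct taxa amplified, the
#' mean pairwise nucleotide difference between amplicons of the same taxon
#' (from a center-star alignment of all inserts) and the mean number of
#' distinct taxa sharing each unique insert sequence. At the species rank the
#' last metric is the "species per unique sequence" statistic: values near 1
#' mean most amplicon sequences identify a single species.
#'
#' @param amplicons An `amplicon_set` (one assay).
#' @return Data frame with columns `rank`, `distinct_taxa`,
#'   `mean_within_taxon_pairwise_diff`, `mean_species_per_unique_sequence`.
#' @export
resolution_summary <- function(amplicons) {
  ranks <- rank_ladder()
  if (nrow(amplicons) == 0) {
    return(data.frame(rank = ranks, distinct_taxa = 0L,
                      mean_within_taxon_pairwise_diff = NA_real_,
                      mean_species_per_unique_sequence = NA_real_))
  }
  ids <- amplicon_ids(amplicons)
  dm <- if (nrow(amplicons) >= 2) {
    msa_distance_matrix(center_star_align(setNames(amplicons$insert_seq, ids)))
  } else NULL
  out <- lapply(ranks, function(r) {
    taxon <- amplicons[[r]]
    known <- taxon != ""
    # mean difference over all within-taxon pairs, pooled across taxa
    within <- NA_real_
    if (!is.null(dm)) {
      pairs <- which(outer(taxon, taxon, "==") &
                       outer(known, known, "&") &
                       upper.tri(dm), arr.ind = TRUE)
      if (nrow(pairs)) within <- mean(dm[pairs])
    }
    # distinct taxa carrying each unique insert sequence
    per_seq <- tapply(taxon[known], amplicons$insert_seq[known],
                      function(tx) length(unique(tx)))
    data.frame(rank = r,
               distinct_taxa = length(unique(taxon[known])),
               mean_within_taxon_pairwise_diff = within,
               mean_species_per_unique_sequence =
                 if (length(per_seq)) mean(per_seq) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
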