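# Independent oracles and shared fixtures for the test suite.

# --- fixtures ----------------------------------------------------------------

# a small mixed database: 4 thrushes (family Turdidae) + 3 mammals + 3 fish
tiny_db <- function() {
  lin <- function(id, class, order, family, genus, species) {
    data.frame(id = id, superkingdom = "Eukaryota", phylum = "Chordata",
               class = class, order = order, family = family, genus = genus,
               species = species)
  }
  lineages <- rbind(
    lin("t1", "Aves", "Passeriformes", "Turdidae", "Turdus", "Turdus migratorius"),
    lin("t2", "Aves", "Passeriformes", "Turdidae", "Turdus", "Turdus merula"),
    lin("t3", "Aves", "Passeriformes", "Turdidae", "Catharus", "Catharus guttatus"),
    lin("t4", "Aves", "Passeriformes", "Turdidae", "Catharus", "Catharus fuscescens"),
    lin("m1", "Mammalia", "Rodentia", "Castoridae", "Castor", "Castor canadensis"),
    lin("m2", "Mammalia", "Rodentia", "Cricetidae", "Ondatra", "Ondatra zibethicus"),
    lin("m3", "Mammalia", "Carnivora", "Procyonidae", "Procyon", "Procyon lotor"),
    lin("f1", "Actinopterygii", "Cypriniformes", "Cyprinidae", "Cyprinus", "Cyprinus carpio"),
    lin("f2", "Actinopterygii", "Cypriniformes", "Cyprinidae", "Campostoma", "Campostoma anomalum"),
    lin("f3", "Actinopterygii", "Cypriniformes", "Catostomidae", "Moxostoma", "Moxostoma anisurum"))
  set.seed(42)
  records <- data.frame(
    id = lineages$id,
    description = paste(lineages$species, "marker"),
    seq = vapply(seq_len(nrow(lineages)), function(i) {
      paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    }, character(1)))
  build_db(records, lineages)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- brute-force primer matching oracle -------------------------------------

iupac_tab <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

bf_match_one_strand <- function(ref, pattern, max_mm, tail_positions) {
  rc <- strsplit(ref, "")[[1]]
  pc <- strsplit(pattern, "")[[1]]
  m <- length(pc)
  hits <- NULL
  for (off in 0:(length(rc) - m)) {
    mm <- 0L; tail_mm <- 0L
    for (k in seq_len(m)) {
      ok <- rc[off + k] %in% iupac_tab[[pc[k]]]
      if (!ok) {
        mm <- mm + 1L
        if (k %in% tail_positions) tail_mm <- tail_mm + 1L
      }
    }
    if (mm <= max_mm && tail_mm == 0L) {
      hits <- rbind(hits, data.frame(start = off, end = off + m,
                                     mismatches = mm))
    }
  }
  hits
}

bf_match_primer <- function(ref, primer, max_mm = 2, t3 = 2) {
  m <- nchar(primer)
  plus <- bf_match_one_strand(ref, primer, max_mm,
                              if (t3 > 0) (m - t3 + 1):m else integer(0))
  minus <- bf_match_one_strand(ref, amplitree::revcomp(primer), max_mm,
                               seq_len(t3))
  out <- NULL
  if (!is.null(plus)) out <- rbind(out, cbind(strand = "+", plus))
  if (!is.null(minus)) out <- rbind(out, cbind(strand = "-", minus))
  out
}

# --- independent glocal alignment oracle (plain R DP) ------------------------

# minimize edits, then gaps, then maximize matches (lexicographic)
r_glocal <- function(q, r) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  m <- length(qc); n <- length(rc)
  E <- matrix(0L, m + 1, n + 1)
  G <- matrix(0L, m + 1, n + 1)
  M <- matrix(0L, m + 1, n + 1)
  E[, 1] <- 0:m; G[, 1] <- 0:m
  for (i in seq_len(m)) for (j in seq_len(n)) {
    mt <- qc[i] == rc[j] && qc[i] != "N" && rc[j] != "N"
    cand <- rbind(c(E[i, j] + !mt, G[i, j], M[i, j] + mt),
                  c(E[i, j + 1] + 1L, G[i, j + 1] + 1L, M[i, j + 1]),
                  c(E[i + 1, j] + 1L, G[i + 1, j] + 1L, M[i + 1, j]))
    pick <- order(cand[, 1], cand[, 2], -cand[, 3])[1]
    E[i + 1, j + 1] <- cand[pick, 1]
    G[i + 1, j + 1] <- cand[pick, 2]
    M[i + 1, j + 1] <- cand[pick, 3]
  }
  final <- cbind(E[m + 1, ], G[m + 1, ], M[m + 1, ])
  pick <- order(final[, 1], final[, 2], -final[, 3])[1]
  c(edits = final[pick, 1], matches = final[pick, 3])
}

# --- additive distance matrices from random trees ----------------------------

random_additive_dm <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_tips, br = NULL))
  tr$edge.length <- sample(1:10, nrow(tr$edge), replace = TRUE)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

# --- presence/absence vs. ground truth ---------------------------------------

# align an observed presence_matrix to the ground-truth matrix (species never
# observed become all-absent columns) and count calls for species outside the
# truth's species set
presence_vs_truth <- function(pm, truth) {
  obs <- matrix(FALSE, nrow(truth), ncol(truth), dimnames = dimnames(truth))
  common <- intersect(colnames(truth), colnames(pm$presence))
  obs[, common] <- pm$presence[rownames(truth), common]
  extra <- setdiff(colnames(pm$presence), colnames(truth))
  extra_calls <- if (length(extra)) {
    sum(pm$presence[rownames(truth), extra])
  } else 0
  list(obs = obs, extra_calls = extra_calls)
}

# --- read simulation for merge round-trips -----------------------------------

reads_from_fragment <- function(frag, read_len = 250) {
  L <- nchar(frag)
  r1 <- substr(frag, 1, min(read_len, L))
  r2 <- substr(amplitree::revcomp(frag), 1, min(read_len, L))
  data.frame(id = "frag", assay = "x",
             r1_insert = r1, r1_qual = strrep("F", nchar(r1)),
             r2_insert = r2, r2_qual = strrep("F", nchar(r2)))
}
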