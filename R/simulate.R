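# ---- simulation configuration ----------------------------------------------

#' Default simulated assay panel
#'
#' Three taxon-targeted assays mirroring a typical multi-marker eDNA panel:
#' a mammal-type mitochondrial rRNA assay (~100 bp inserts), a fish-type
#' cytochrome-b assay (~160 bp) and a plant-type trnL assay with very short
#' inserts (~48 bp, per-assay minimum read length 17 bp), each tied to its
#' own target class. One forward primer carries a degenerate position so the
#' degenerate machinery is exercised end to end.
#'
#' @return Data frame with assay, target lineage and primer columns.
#' @export
sim_clades <- function() {
  data.frame(
    assay = c("mamm16S", "fishCytb", "plantTrnL"),
    phylum = c("Chordata", "Chordata", "Streptophyta"),
    class = c("Mammalia", "Actinopterygii", "Magnoliopsida"),
    forward = c("CGGTTGGGGTGACCTCGGAG", "TGACTTGARAAACCACCGTT",
                "GGGCAATCCTGAGCCAAATC"),
    reverse = c("GCTGTTATCCCTAGGGTAAC", "CTCCGATCTCCGGATTACAA",
                "CCATTGAGTCTCTGCACCTA"),
    insert_len = c(100L, 160L, 48L),
    min_read_len = c(50L, 50L, 17L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the study conditions a synthetic run is generated under: the
#' shape of the taxonomy (families/genera/species per target clade), the
#' per-level divergence of the marker inserts, the assay panel, and the
#' sequencing layout (samples, depth, error rate, read length).
#'
#' @param seed Master seed; every random step derives from it.
#' @param n_families,n_genera_per_family,n_species_per_genus Taxonomy shape
#'   per target clade (defaults 2/2/2, i.e. 8 species per clade).
#' @param divergence Named vector of per-level substitution probabilities for
#'   the star-shaped evolution of the marker insert (defaults: family 0.12,
#'   genus 0.05, species 0.02, so within-genus distances are smaller than
#'   within-family distances in expectation).
#' @param flank_len Length of random flanking sequence on each side of the
#'   amplicon in every reference record (default 30 bp).
#' @param clades Assay/clade table, see [sim_clades()].
#' @param n_samples Number of real (non-control) samples (default 12).
#' @param n_controls Number of blank extraction controls (default 2).
#' @param depth Read pairs per real sample (default 5000).
#' @param species_per_sample Range of species per sample (default 3-6).
#' @param error_rate Per-base substitution error probability in `[0, 0.05]`
#'   (default 0.005, a MiSeq-like rate).
#' @param read_length Read length in bp (default 250).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_families = 2L, n_genera_per_family = 2L,
                       n_species_per_genus = 2L,
                       divergence = c(family = 0.12, genus = 0.05,
                                      species = 0.02),
                       flank_len = 30L, clades = sim_clades(),
                       n_samples = 12L, n_controls = 2L, depth = 5000L,
                       species_per_sample = 3:6, error_rate = 0.005,
                       read_length = 250L) {
  stopifnot(error_rate >= 0, error_rate <= 0.05,
            all(c("family", "genus", "species") %in% names(divergence)))
  if (max(divergence) > 0.3) {
    stop("divergence above 0.3 substitutions/site would saturate the insert ",
         "and destroy the primer-flanked amplicon structure", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 n_genera_per_family = as.integer(n_genera_per_family),
                 n_species_per_genus = as.integer(n_species_per_genus),
                 divergence = divergence, flank_len = as.integer(flank_len),
                 clades = clades, n_samples = as.integer(n_samples),
                 n_controls = as.integer(n_controls), depth = as.integer(depth),
                 species_per_sample = species_per_sample,
                 error_rate = error_rate,
                 read_length = as.integer(read_length)),
            class = "sim_config")
}

# panel corresponding to a clade table
sim_panel <- function(clades) {
  primer_panel(data.frame(assay = clades$assay, forward = clades$forward,
                          reverse = clades$reverse, min_product = 50L,
                          max_product = 3000L,
                          min_read_len = clades$min_read_len))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# i.i.d. substitution at the given per-site rate
mutate_seq <- function(seq, rate) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3, length(hit), replace = TRUE)
    ch[hit] <- bases[((match(ch[hit], bases) - 1L + shift) %% 4L) + 1L]
  }
  paste(ch, collapse = "")
}

# one concrete realization of a degenerate primer
realize_iupac <- function(primer) {
  sets <- iupac_sets()[strsplit(primer, "", fixed = TRUE)[[1]]]
  paste(vapply(sets, function(s) s[sample.int(length(s), 1)], character(1)),
        collapse = "")
}

# ---- reference database -----------------------------------------------------

#' Simulate a taxonomy-structured reference database
#'
#' For each assay clade a root marker insert evolves down a fixed star-shaped
#' taxonomy (clade -> families -> genera -> species) by i.i.d. substitution,
#' so within-genus distances are smaller than within-family distances in
#' expectation. Each reference record embeds the assay's primer binding
#' sites exactly (one concrete realization of any degenerate position)
#' flanking the species insert, surrounded by random flanks. Species inserts
#' are guaranteed distinct within an assay. Deterministic per seed.
#'
#' @param config A [sim_config()].
#' @return List with `db` (a `reference_db`), `panel` (the matching
#'   [primer_panel()]) and `truth` (data frame `assay`, `species`, `ref_id`,
#'   `insert`, `amplicon`).
#' @export
simulate_reference_db <- function(config = sim_config()) {
  withr::with_seed(config$seed, {
    recs <- list(); lins <- list(); truth <- list()
    for (ci in seq_len(nrow(config$clades))) {
      cl <- config$clades[ci, ]
      fwd_site <- realize_iupac(cl$forward)
      rev_site <- realize_iupac(cl$reverse)
      root <- random_dna(cl$insert_len)
      inserts <- character(0); meta <- list()
      for (f in seq_len(config$n_families)) {
        fam_seq <- mutate_seq(root, config$divergence[["family"]])
        for (g in seq_len(config$n_genera_per_family)) {
          gen_seq <- mutate_seq(fam_seq, config$divergence[["genus"]])
          for (s in seq_len(config$n_species_per_genus)) {
            sp_seq <- mutate_seq(gen_seq, config$divergence[["species"]])
            inserts <- c(inserts, sp_seq)
            meta[[length(meta) + 1]] <- c(f = f, g = g, s = s)
          }
        }
      }
      # enforce distinct species inserts within the assay
      tries <- 0
      while (anyDuplicated(inserts)) {
        tries <- tries + 1
        if (tries > 100) {
          stop("could not generate distinct species inserts for assay ",
               cl$assay, call. = FALSE)
        }
        dup <- which(duplicated(inserts))
        inserts[dup] <- vapply(inserts[dup], mutate_seq, character(1),
                               rate = max(config$divergence[["species"]],
                                          0.02))
      }
      for (k in seq_along(inserts)) {
        m <- meta[[k]]
        genus <- sprintf("%s_gen%d_%d", cl$assay, m["f"], m["g"])
        species <- sprintf("%s sp%d", genus, m["s"])
        ref_id <- sprintf("%s_f%dg%ds%d", cl$assay, m["f"], m["g"], m["s"])
        amplicon <- paste0(fwd_site, inserts[k], revcomp(rev_site))
        recs[[length(recs) + 1]] <- data.frame(
          id = ref_id,
          description = sprintf("%s %s marker", species, cl$assay),
          seq = paste0(random_dna(config$flank_len), amplicon,
                       random_dna(config$flank_len)))
        lins[[length(lins) + 1]] <- data.frame(
          id = ref_id, superkingdom = "Eukaryota", phylum = cl$phylum,
          class = cl$class, order = sprintf("%s_ord%d", cl$assay, m["f"]),
          family = sprintf("%s_fam%d", cl$assay, m["f"]), genus = genus,
          species = species)
        truth[[length(truth) + 1]] <- data.frame(
          assay = cl$assay, species = species, ref_id = ref_id,
          insert = inserts[k], amplicon = amplicon)
      }
    }
    db <- build_db(do.call(rbind, recs), do.call(rbind, lins))
    list(db = db, panel = sim_panel(config$clades),
         truth = do.call(rbind, truth))
  })
}

# ---- reads ------------------------------------------------------------------

sim_adapter <- function(n) {
  ad <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCACGTAGCTAGCTAGGTCA"
  substr(strrep(ad, ceiling(n / nchar(ad))), 1, n)
}

# apply substitution errors to equal-length templates; Phred 37 everywhere,
# erroneous bases get a quality dip to Phred 15
apply_errors <- function(templates, rate) {
  n <- length(templates)
  if (n == 0) return(list(seq = character(0), qual = character(0)))
  L <- nchar(templates[1])
  if (rate == 0) {
    return(list(seq = templates, qual = rep(strrep("F", L), n)))
  }
  m <- do.call(rbind, strsplit(templates, "", fixed = TRUE))
  q <- matrix("F", n, L)
  hit <- which(matrix(runif(n * L) < rate, n, L))
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3, length(hit), replace = TRUE)
    m[hit] <- bases[((match(m[hit], bases) - 1L + shift) %% 4L) + 1L]
    q[hit] <- "0" # Phred 15
  }
  list(seq = apply(m, 1, paste, collapse = ""),
       qual = apply(q, 1, paste, collapse = ""))
}

#' Simulate all reads of one sample
#'
#' Each read pair picks a species according to the sample composition and an
#' assay uniformly among the assays amplifying that species; read 1 starts at
#' the forward primer, read 2 at the reverse primer of the amplicon, with
#' synthetic adapter filling any read-through beyond a short amplicon.
#' Substitution errors are applied at `config$error_rate` to the reads and
#' the index read.
#'
#' @param truth `truth` table from [simulate_reference_db()].
#' @param spec List with `sample_id`, `index`, `depth` and `composition`
#'   (named numeric vector of species fractions summing to 1; empty means a
#'   blank sample yielding zero reads).
#' @param config The [sim_config()].
#' @param seed Seed for this sample's randomness.
#' @return Data frame in [read_fastq_run()] layout.
#' @export
simulate_sample <- function(truth, spec, config, seed = config$seed) {
  empty <- data.frame(id = character(0), r1_seq = character(0),
                      r1_qual = character(0), r2_seq = character(0),
                      r2_qual = character(0), index_seq = character(0))
  if (length(spec$composition) == 0 || spec$depth == 0) return(empty)
  stopifnot(abs(sum(spec$composition) - 1) < 1e-8,
            all(names(spec$composition) %in% truth$species))
  withr::with_seed(seed, {
    species <- sample(names(spec$composition), spec$depth, replace = TRUE,
                      prob = spec$composition)
    rows_of <- split(seq_len(nrow(truth)), truth$species)
    row <- vapply(species, function(sp) {
      cand <- rows_of[[sp]]
      if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    }, integer(1))
    amp <- truth$amplicon[row]
    L <- config$read_length
    pad <- sim_adapter(L)
    r1_tpl <- substr(paste0(amp, pad), 1, L)
    r2_tpl <- substr(paste0(revcomp(amp), pad), 1, L)
    r1 <- apply_errors(r1_tpl, config$error_rate)
    r2 <- apply_errors(r2_tpl, config$error_rate)
    ix <- apply_errors(rep(spec$index, spec$depth), config$error_rate)
    data.frame(id = sprintf("%s_r%06d", spec$sample_id,
                            seq_len(spec$depth)),
               r1_seq = r1$seq, r1_qual = r1$qual,
               r2_seq = r2$seq, r2_qual = r2$qual,
               index_seq = ix$seq, stringsAsFactors = FALSE)
  })
}

# ---- whole study ------------------------------------------------------------

#' Simulate a complete multiplexed eDNA sequencing run
#'
#' Generates the reference database, an index set (pairwise Hamming distance
#' >= 2), per-sample compositions with every species fraction above ~2%, the
#' reads of every sample plus blank extraction controls, and the ground
#' truth. Regenerating with the same config is byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, `r1.fastq`, `r2.fastq`,
#'   `index.fastq`, `ref.fasta`, `taxonomy.tsv`, `panel.tsv`,
#'   `sample_sheet.tsv` and a `manifest.json` tying truth to files are
#'   written there.
#' @return List with `db`, `panel`, `truth`, `sheet` (a [sample_sheet()]),
#'   `pairs` (all reads), `compositions` (named list per sample) and
#'   `presence` (logical ground-truth matrix sample x species over non-blank
#'   samples).
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  ref <- simulate_reference_db(config)
  n_total <- config$n_samples + config$n_controls
  indices <- design_index_set(n_total, length = 6, min_dist = 2,
                              seed = config$seed + 1L)
  regions <- c("upper", "middle", "lower")
  sheet <- sample_sheet(data.frame(
    index = indices,
    sample_id = c(sprintf("S%02d", seq_len(config$n_samples)),
                  sprintf("CTRL%d", seq_len(config$n_controls))),
    site = c(sprintf("site%02d", seq_len(config$n_samples)),
             rep("control", config$n_controls)),
    region = c(regions[(seq_len(config$n_samples) - 1) %% 3 + 1],
               rep("", config$n_controls)),
    timepoint = c(ifelse(seq_len(config$n_samples) <=
                           ceiling(config$n_samples / 2),
                         "before", "after"),
                  rep("", config$n_controls))))
  all_species <- unique(ref$truth$species)
  compositions <- withr::with_seed(config$seed + 2L, {
    lapply(seq_len(config$n_samples), function(i) {
      k <- if (length(config$species_per_sample) == 1) {
        config$species_per_sample
      } else sample(config$species_per_sample, 1)
      sp <- sample(all_species, min(k, length(all_species)))
      w <- runif(length(sp), 1, 10) # min fraction ~2% at 6 species
      setNames(w / sum(w), sp)
    })
  })
  names(compositions) <- sheet$sample_id[seq_len(config$n_samples)]
  pairs <- list()
  for (i in seq_len(n_total)) {
    comp <- if (i <= config$n_samples) compositions[[i]] else numeric(0)
    depth <- if (i <= config$n_samples) config$depth else 0L
    spec <- list(sample_id = sheet$sample_id[i], index = sheet$index[i],
                 depth = depth, composition = comp)
    pairs[[i]] <- simulate_sample(ref$truth, spec, config,
                                  seed = config$seed + 100L + i)
  }
  pairs <- do.call(rbind, pairs)
  presence <- matrix(FALSE, config$n_samples, length(all_species),
                     dimnames = list(names(compositions), sort(all_species)))
  for (s in names(compositions)) {
    presence[s, names(compositions[[s]])] <- TRUE
  }
  presence <- presence[, sort(colnames(presence)), drop = FALSE]
  out <- list(db = ref$db, panel = ref$panel, truth = ref$truth,
              sheet = sheet, pairs = pairs, compositions = compositions,
              presence = presence)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_fastq(pairs$id, pairs$r1_seq, pairs$r1_qual, p("r1.fastq"))
    write_fastq(pairs$id, pairs$r2_seq, pairs$r2_qual, p("r2.fastq"))
    write_fastq(pairs$id, pairs$index_seq,
                strrep("F", nchar(pairs$index_seq)), p("index.fastq"))
    write_reference_db(ref$db, p("ref.fasta"), p("taxonomy.tsv"))
    write.table(as.data.frame(ref$panel), p("panel.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(sheet), p("sample_sheet.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, depth = config$depth,
           error_rate = config$error_rate,
           files = list(r1 = "r1.fastq", r2 = "r2.fastq",
                        index = "index.fastq", reference = "ref.fasta",
                        taxonomy = "taxonomy.tsv", panel = "panel.tsv",
                        sample_sheet = "sample_sheet.tsv"),
           composition = lapply(compositions, as.list)),
      p("manifest.json"), auto_unbox = TRUE, digits = NA)
    out$dir <- out_dir
  }
  out
}
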