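derep_from_counts <- function(...) {
  # build a derep_set from named sequence -> per-sample count vectors
  specs <- list(...)
  rows <- do.call(rbind, lapply(names(specs), function(sq) {
    counts <- specs[[sq]]
    do.call(rbind, lapply(names(counts), function(s) {
      if (counts[[s]] == 0) return(NULL)
      data.frame(sample_id = s, assay = "mamm",
                 seq = rep(sq, counts[[s]]))
    }))
  }))
  dereplicate(rows)
}

test_that("the 10-reads-total filter removes 9 and keeps 10", {
  d <- derep_from_counts(ACGTACGTAC = list(s1 = 4, s2 = 5),   # 9 total
                         GGGGCCCCGG = list(s1 = 5, s2 = 5))   # 10 total
  out <- filter_low_count(d, min_total = 10)
  expect_equal(out$kept$seqs$sequence, "GGGGCCCCGG")
  expect_equal(out$removed$seqs$sequence, "ACGTACGTAC")
  expect_equal(nrow(out$kept$seqs) + nrow(out$removed$seqs), nrow(d$seqs))
  expect_equal(out$removed_read_fraction, 9 / 19)
  # empty input stays empty
  empty <- dereplicate(data.frame(sample_id = character(0),
                                  assay = character(0), seq = character(0)))
  out2 <- filter_low_count(empty)
  expect_equal(nrow(out2$kept$seqs), 0)
  expect_equal(nrow(out2$removed$seqs), 0)
})

test_that("best-hit assignment keeps ties and applies the strict >90% rule", {
  set.seed(61)
  shared <- rand_dna(100)
  other <- rand_dna(100)
  lin <- function(id, sp) {
    data.frame(id = id, superkingdom = "E", phylum = "P", class = "C",
               order = "O", family = "F", genus = "G", species = sp)
  }
  # two references share one marker sequence (distinct species), one differs
  db <- build_db(
    data.frame(id = c("r1", "r2", "r3"), description = "",
               seq = c(paste0(rand_dna(10), shared, rand_dna(10)),
                       paste0(rand_dna(10), shared, rand_dna(10)),
                       paste0(rand_dna(10), other, rand_dna(10)))),
    rbind(lin("r1", "Species one"), lin("r2", "Species two"),
          lin("r3", "Species three")))
  names_fix <- list(); names_fix[[shared]] <- list(s1 = 12)
  d <- do.call(derep_from_counts, names_fix)
  asn <- assign_best_hit(d, db)
  expect_equal(asn$status, "assigned")
  expect_equal(asn$best_identity, 1.0)
  expect_equal(asn$species[[1]], c("Species one", "Species two"))
  # an exact match to r3 yields only its species
  names_fix <- list(); names_fix[[other]] <- list(s1 = 12)
  asn3 <- assign_best_hit(do.call(derep_from_counts, names_fix), db)
  expect_equal(asn3$species[[1]], "Species three")
})

test_that("identity exactly at the threshold is unassigned, just above is assigned", {
  set.seed(67)
  insert <- rand_dna(100)
  lin <- data.frame(id = "r1", superkingdom = "E", phylum = "P", class = "C",
                    order = "O", family = "F", genus = "G",
                    species = "Only species")
  db <- build_db(data.frame(id = "r1", description = "",
                            seq = paste0("TTTTT", insert, "TTTTT")), lin)
  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b) setdiff(c("A", "C", "G", "T"),
                                                   b)[1], character(1))
    paste(ch, collapse = "")
  }
  q90 <- mutate_at(insert, seq(5, 95, by = 10))  # 10 substitutions
  q91 <- mutate_at(insert, seq(5, 85, by = 10))  # 9 substitutions
  names_fix <- list(); names_fix[[q90]] <- list(s1 = 12)
  d90 <- do.call(derep_from_counts, names_fix)
  asn90 <- assign_best_hit(d90, db, identity_threshold = 0.90)
  expect_equal(asn90$best_identity, 0.90)
  expect_equal(asn90$status, "unassigned")
  expect_equal(asn90$species[[1]], character(0))
  names_fix <- list(); names_fix[[q91]] <- list(s1 = 12)
  asn91 <- assign_best_hit(do.call(derep_from_counts, names_fix), db,
                           identity_threshold = 0.90)
  expect_equal(asn91$best_identity, 0.91)
  expect_equal(asn91$status, "assigned")
})

test_that("best-hit assignment equals a brute-force identity scan", {
  set.seed(71)
  ref <- simulate_reference_db(sim_config(seed = 71))
  db <- ref$db
  queries <- c(ref$truth$insert[c(3, 10, 17)], rand_dna(80))
  names_fix <- setNames(lapply(queries, function(q) list(s1 = 15)), queries)
  d <- do.call(derep_from_counts, names_fix)
  asn <- assign_best_hit(d, db)
  for (i in seq_len(nrow(asn))) {
    ident <- vapply(db$seq, function(r) glocal_identity(asn$sequence[i], r),
                    numeric(1))
    expect_equal(asn$best_identity[i], max(ident))
    if (max(ident) > 0.9) {
      expect_equal(asn$species[[i]],
                   sort(unique(db$species[ident == max(ident)])))
    }
  }
})

test_that("presence calls need 10 reads per sample, summed across sequences", {
  set.seed(73)
  sq1 <- rand_dna(90); sq2 <- rand_dna(90)
  lin <- data.frame(id = c("r1", "r2"), superkingdom = "E", phylum = "P",
                    class = "C", order = "O", family = "F", genus = "G",
                    species = c("Castor canadensis", "Procyon lotor"))
  db <- build_db(data.frame(id = c("r1", "r2"), description = "",
                            seq = c(sq1, sq2)), lin)
  # beaver: 6 + 5 reads in s1 (-> 11, present), 9 in s2 (-> absent);
  # the two unique beaver sequences differ by one substitution
  sq1b <- sq1; substr(sq1b, 40, 40) <- setdiff(c("A", "C", "G", "T"),
                                               substr(sq1, 40, 40))[1]
  names_fix <- list()
  names_fix[[sq1]] <- list(s1 = 6, s2 = 9)
  names_fix[[sq1b]] <- list(s1 = 5)
  names_fix[[sq2]] <- list(s2 = 10)
  d <- do.call(derep_from_counts, names_fix)
  asn <- assign_best_hit(d, db)
  pm <- presence_matrix(asn, d, min_reads_per_sample = 10)
  expect_true(pm$presence["s1", "Castor canadensis"])
  expect_false(pm$presence["s2", "Castor canadensis"])
  expect_equal(pm$counts["s2", "Castor canadensis"], 9L)
  expect_true(pm$presence["s2", "Procyon lotor"])
  expect_false(pm$presence["s1", "Procyon lotor"])
})

test_that("presence is monotone: adding reads never removes a call", {
  set.seed(79)
  sq <- rand_dna(90)
  lin <- data.frame(id = "r1", superkingdom = "E", phylum = "P", class = "C",
                    order = "O", family = "F", genus = "G", species = "Sp a")
  db <- build_db(data.frame(id = "r1", description = "", seq = sq), lin)
  for (n in c(10, 25, 100)) {
    names_fix <- list(); names_fix[[sq]] <- list(s1 = n)
    d <- do.call(derep_from_counts, names_fix)
    pm <- presence_matrix(assign_best_hit(d, db), d)
    expect_true(pm$presence["s1", "Sp a"])
  }
})

test_that("expected read counts follow the abundance x depth arithmetic", {
  expect_equal(expected_read_count(0.01, 14211), 142L)
  expect_equal(expected_read_count(0, 5000), 0L)
  expect_equal(expected_read_count(1, 5000), 5000L)
})

test_that("Fisher association matches hand enumeration and is symmetric", {
  # balanced table: no association
  expect_equal(fisher_association(c(TRUE, TRUE, FALSE, FALSE),
                                  c("a", "b", "a", "b")), 1.0)
  # [[5,0],[0,5]]: two-sided p = 2 / choose(10,5) = 2/252
  present <- rep(c(TRUE, FALSE), each = 5)
  group <- rep(c("a", "b"), each = 5)
  expect_equal(fisher_association(present, group), 2 / 252)
  # swapping the rows leaves p unchanged
  expect_equal(fisher_association(!present, group), 2 / 252)
  # degenerate margins warn and return 1
  expect_warning(p <- fisher_association(rep(TRUE, 4), c("a", "a", "b", "b")),
                 "degenerate")
  expect_equal(p, 1)
})
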