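test_that("index design yields distinct indices at the required distance", {
  idx <- design_index_set(96, length = 6, min_dist = 2, seed = 5)
  expect_length(idx, 96)
  expect_length(unique(idx), 96)
  # brute-force verification of the minimum pairwise Hamming distance
  chars <- do.call(rbind, strsplit(idx, ""))
  dists <- c()
  for (i in 1:95) for (j in (i + 1):96) {
    dists <- c(dists, sum(chars[i, ] != chars[j, ]))
  }
  expect_gte(min(dists), 2)
  expect_identical(idx, design_index_set(96, length = 6, min_dist = 2,
                                         seed = 5))
  expect_error(design_index_set(2, length = 1, min_dist = 2), "infeasible")
})

test_that("sample sheets enforce the index design constraints", {
  ok <- data.frame(index = c("AAAAAA", "CCAAAA"), sample_id = c("s1", "s2"))
  expect_s3_class(sample_sheet(ok), "sample_sheet")
  bad <- data.frame(index = c("AAAAAA", "CAAAAA"), sample_id = c("s1", "s2"))
  expect_error(sample_sheet(bad), "Hamming")
  expect_error(sample_sheet(data.frame(index = c("AAAAAA", "AAAAAA"),
                                       sample_id = c("s1", "s2"))),
               "duplicate")
})

test_that("exact demultiplexing assigns, rejects 1-mismatch indices and conserves reads", {
  sheet <- sample_sheet(data.frame(index = c("AAAAAA", "CCAAAA"),
                                   sample_id = c("s1", "s2")))
  pairs <- data.frame(id = c("r1", "r2", "r3"),
                      r1_seq = "ACGT", r1_qual = "FFFF",
                      r2_seq = "ACGT", r2_qual = "FFFF",
                      index_seq = c("AAAAAA", "AAAAAC", "CCAAAA"))
  out <- demultiplex(pairs, sheet)
  expect_equal(out$s1$id, "r1")
  expect_equal(out$s2$id, "r3")
  expect_equal(out$unassigned$id, "r2") # one mismatch stays unassigned
  # conservation on random input
  set.seed(23)
  rnd <- data.frame(id = paste0("x", 1:200), r1_seq = "A", r1_qual = "F",
                    r2_seq = "A", r2_qual = "F",
                    index_seq = vapply(1:200, function(i) rand_dna(6),
                                       character(1)))
  out2 <- demultiplex(rnd, sheet)
  expect_equal(sum(vapply(out2, nrow, integer(1))), 200)
})

sim_pair <- function(fwd, rev, insert, read_len = 250, offset1 = 0,
                     offset2 = 0, id = "p1") {
  amp <- paste0(fwd, insert, amplitree::revcomp(rev))
  pad <- strrep("AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC", 10)
  r1 <- substr(paste0(strrep("T", offset1), amp, pad), 1, read_len)
  r2 <- substr(paste0(strrep("T", offset2), amplitree::revcomp(amp), pad),
               1, read_len)
  data.frame(id = id, r1_seq = r1, r1_qual = strrep("F", nchar(r1)),
             r2_seq = r2, r2_qual = strrep("F", nchar(r2)))
}

test_panel <- function() {
  primer_panel(data.frame(
    assay = c("mamm", "plant"),
    forward = c("CGGTTGGGGTGACCTCGGAG", "GGGCAATCCTGAGCCAAATC"),
    reverse = c("GCTGTTATCCCTAGGGTAAC", "CCATTGAGTCTCTGCACCTA"),
    min_product = 50L, max_product = 3000L, min_read_len = c(50L, 17L)))
}

test_that("primer identification trims constructed read pairs exactly", {
  set.seed(29)
  panel <- test_panel()
  insert <- rand_dna(100)
  pairs <- sim_pair(panel$forward[1], panel$reverse[1], insert)
  tr <- identify_and_trim(pairs, panel)
  expect_equal(nrow(tr$trimmed), 1)
  expect_equal(tr$trimmed$assay, "mamm")
  expect_equal(tr$trimmed$fwd_mismatches, 0L)
  expect_equal(tr$trimmed$rev_mismatches, 0L)
  # read-through beyond the 100 bp amplicon was removed from both mates
  expect_equal(tr$trimmed$r1_insert, insert)
  expect_equal(tr$trimmed$r2_insert, revcomp(insert))
  expect_equal(nchar(tr$trimmed$r1_qual), nchar(tr$trimmed$r1_insert))
  # a 5' offset up to 5 bases is tolerated
  off <- identify_and_trim(sim_pair(panel$forward[1], panel$reverse[1],
                                    insert, offset1 = 5, offset2 = 3), panel)
  expect_equal(off$trimmed$r1_insert, insert)
})

test_that("a 48 bp short amplicon is read-through-trimmed to 48 bp", {
  set.seed(30)
  panel <- test_panel()
  insert <- rand_dna(48)
  pairs <- sim_pair(panel$forward[2], panel$reverse[2], insert)
  tr <- identify_and_trim(pairs, panel)
  expect_equal(nchar(tr$trimmed$r1_insert), 48)
  expect_equal(tr$trimmed$r1_insert, insert)
  expect_equal(tr$trimmed$r2_insert, revcomp(insert))
})

test_that("unmatched and ambiguous pairs are rejected with reasons", {
  set.seed(31)
  panel <- test_panel()
  noise <- data.frame(id = "n1", r1_seq = rand_dna(250),
                      r1_qual = strrep("F", 250), r2_seq = rand_dna(250),
                      r2_qual = strrep("F", 250))
  tr <- identify_and_trim(noise, panel)
  expect_equal(tr$rejected$reason, "no_primer")
  # two assays sharing identical primers tie exactly -> ambiguous
  twin <- primer_panel(data.frame(
    assay = c("a1", "a2"), forward = panel$forward[1],
    reverse = panel$reverse[1], min_product = 50L, max_product = 3000L,
    min_read_len = 50L))
  amb <- identify_and_trim(sim_pair(panel$forward[1], panel$reverse[1],
                                    rand_dna(100)), twin)
  expect_equal(amb$rejected$reason, "ambiguous")
  expect_equal(nrow(amb$trimmed), 0)
})

test_that("length filters apply per-assay minima and the 5 bp pair rule", {
  panel <- test_panel()
  row <- function(assay, l1, l2) {
    data.frame(id = paste(assay, l1, l2), assay = assay,
               r1_insert = strrep("A", l1), r1_qual = strrep("F", l1),
               r2_insert = strrep("T", l2), r2_qual = strrep("F", l2),
               fwd_mismatches = 0L, rev_mismatches = 0L)
  }
  trimmed <- rbind(row("mamm", 49, 49),   # below the 50 bp default
                   row("mamm", 50, 50),   # exactly at the bound
                   row("plant", 30, 30),  # short assay minimum 17 -> kept
                   row("plant", 16, 16),  # below even the short minimum
                   row("mamm", 100, 106), # pair differs by 6 bp
                   row("mamm", 100, 105)) # 5 bp difference is tolerated
  out <- length_filters(trimmed, panel)
  expect_equal(out$pass$id, c("mamm 50 50", "plant 30 30", "mamm 100 105"))
  expect_equal(out$rejected$reason,
               c("too_short", "too_short", "length_mismatch"))
})

test_that("merging reconstructs fragments and resolves conflicts by quality", {
  set.seed(37)
  # 180 bp fragment, 250 bp reads: full mutual overlap, lossless
  frag <- rand_dna(180)
  expect_equal(merge_pair(reads_from_fragment(frag)), frag)
  # 400 bp fragment: 100 bp overlap in the middle
  frag2 <- rand_dna(400)
  expect_equal(merge_pair(reads_from_fragment(frag2)), frag2)
  # single disagreement: the base with the higher Phred wins
  tr <- reads_from_fragment(rand_dna(120))
  a <- tr$r1_insert
  substr(tr$r1_insert, 60, 60) <- if (substr(a, 60, 60) == "A") "C" else "A"
  q1 <- tr$r1_qual; substr(q1, 60, 60) <- "5" # Phred 20
  tr$r1_qual <- q1 # r2 stays at Phred 37 -> r2 base (the original) wins
  expect_equal(merge_pair(tr), a)
  # on a quality tie the read-1 base wins
  tr$r1_qual <- strrep("F", 120)
  expect_equal(substr(merge_pair(tr), 60, 60), substr(tr$r1_insert, 60, 60))
  # unrelated inserts cannot be merged
  un <- data.frame(id = "u", assay = "x",
                   r1_insert = rand_dna(80), r1_qual = strrep("F", 80),
                   r2_insert = rand_dna(80), r2_qual = strrep("F", 80))
  expect_true(is.na(merge_pair(un)))
})

test_that("error-free simulated pairs merge back to the exact fragment", {
  set.seed(41)
  for (i in 1:50) {
    frag <- rand_dna(sample(60:400, 1))
    expect_equal(merge_pair(reads_from_fragment(frag)), frag)
  }
})

test_that("dereplication counts unique sequences per sample and conserves reads", {
  cons <- data.frame(
    sample_id = c(rep("s1", 7), "s2"),
    assay = "mamm",
    seq = c(rep("ACGTACGT", 5), rep("GGGGCCCC", 2), "ACGTACGT"))
  d <- dereplicate(cons)
  expect_equal(nrow(d$seqs), 2)
  expect_equal(sort(d$seqs$total_reads), c(2, 6))
  shared <- d$seqs$seq_id[d$seqs$sequence == "ACGTACGT"]
  expect_equal(unname(d$counts[shared, c("s1", "s2")]), c(5L, 1L))
  expect_equal(sum(d$counts), nrow(cons))
  # order invariance
  perm <- withr::with_seed(2, sample(nrow(cons)))
  d2 <- dereplicate(cons[perm, ])
  expect_identical(d, d2)
  # same sequence under different assays stays distinct
  cons$assay[8] <- "plant"
  expect_equal(nrow(dereplicate(cons)$seqs), 3)
})

test_that("the pipeline conserves every read through all stages", {
  study <- simulate_study(sim_config(seed = 51, n_samples = 4, depth = 300,
                                     error_rate = 0.01))
  res <- run_read_pipeline(study$pairs, study$sheet, study$panel)
  expect_equal(sum(res$log$n), nrow(study$pairs))
  expect_equal(sum(res$derep$counts),
               res$log$n[res$log$reason == "merged"])
})

test_that("FASTQ round-trip preserves reads, qualities and indices", {
  study <- simulate_study(sim_config(seed = 53, n_samples = 2, depth = 50),
                          out_dir = withr::local_tempdir())
  pairs <- read_fastq_run(file.path(study$dir, "r1.fastq"),
                          file.path(study$dir, "r2.fastq"),
                          file.path(study$dir, "index.fastq"))
  expect_equal(pairs$id, study$pairs$id)
  expect_equal(pairs$r1_seq, study$pairs$r1_seq)
  expect_equal(pairs$r1_qual, study$pairs$r1_qual)
  expect_equal(pairs$index_seq, study$pairs$index_seq)
})
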