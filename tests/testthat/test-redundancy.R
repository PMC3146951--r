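# Random "protein family": a parent sequence plus point-mutated children,
# for clustering property checks.
mutate_seq <- function(s, k) {
  chars <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(chars), k)
  chars[pos] <- vapply(chars[pos], function(old)
    sample(setdiff(AA_STANDARD, old), 1), character(1))
  paste(chars, collapse = "")
}

test_that("fragment removal keeps exactly the records above the cutoff", {
  rec <- protein_records(c("a", "b", "c"),
                         c(strrep("L", 99), strrep("L", 100),
                           strrep("L", 250)))
  kept <- remove_fragments(rec)
  expect_equal(kept$id, c("b", "c"))
  expect_equal(nrow(remove_fragments(rec[0, ])), 0L)
  expect_equal(remove_fragments(rec, min_len = 1), rec)
  expect_identical(remove_fragments(remove_fragments(rec)),
                   remove_fragments(rec))
})

test_that("pairwise identity matches hand-computable alignments", {
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 5)
  expect_equal(pairwise_identity(s, s)$identity, 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC")$identity, 0.0)
  # gap-free optimum: 9 identities over 10 columns
  pi <- pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV")
  expect_equal(pi$identity, 0.9)
  expect_equal(pi$alignment_length, 10)
  # identity denominator includes gap columns
  pi2 <- pairwise_identity(strrep("ACDEFGHIKL", 3),
                           paste0(strrep("ACDEFGHIKL", 3), "WWWWW"))
  expect_equal(pi2$alignment_length, 35)
  expect_equal(pi2$identity, 30 / 35)
})

test_that("selenocysteine and pyrrolysine letters do not break alignment", {
  expect_silent(pi <- pairwise_identity("ACDUFGHIKL", "ACDOFGHIKL"))
  expect_lte(pi$identity, 1.0)
})

test_that("dedupe joins identical records and keeps distinct ones", {
  rec <- protein_records(c("a", "b"), rep(strrep("MKLVHASDE", 20), 2))
  dd <- dedupe(rec)
  expect_equal(nrow(dd$records), 1L)
  expect_equal(dd$assignments$representative_id, c("a", "a"))

  set.seed(2)
  far <- protein_records(c("x", "y", "z"),
                         vapply(1:3, function(i) random_sequence(120),
                                character(1)))
  expect_equal(nrow(dedupe(far)$records), 3L)
})

test_that("greedy order resolves near-threshold chains deterministically", {
  set.seed(8)
  base <- paste(sample(AA_STANDARD, 100, replace = TRUE), collapse = "")
  b <- mutate_seq(base, 4)        # identity 0.96 to base
  cc <- mutate_seq(b, 4)          # 0.96 to b, ~0.92 to base
  rec <- protein_records(c("a", "b", "c"), c(base, b, cc))
  dd <- dedupe(rec, 0.95)
  # equal lengths, lexicographic order: a founds, b joins a, c is below the
  # threshold against the only representative a and founds its own cluster
  expect_equal(dd$records$id, c("a", "c"))
  expect_equal(dd$assignments$representative_id[dd$assignments$member_id == "b"],
               "a")
})

test_that("dedupe leaves no representative pair above the threshold and every
           removed member above it with its representative", {
  set.seed(14)
  seqs <- character(0); ids <- character(0)
  for (fam in 1:4) {
    parent <- paste(sample(AA_STANDARD, sample(100:140, 1), replace = TRUE),
                    collapse = "")
    for (m in 1:4) {
      seqs <- c(seqs, if (m == 1) parent else mutate_seq(parent, sample(1:3, 1)))
      ids <- c(ids, sprintf("f%d_%d", fam, m))
    }
  }
  dd <- dedupe(protein_records(ids, seqs), 0.95)
  reps <- dd$records
  if (nrow(reps) > 1) {
    for (a in 1:(nrow(reps) - 1)) for (b in (a + 1):nrow(reps))
      expect_lte(pairwise_identity(reps$sequence[a],
                                   reps$sequence[b])$identity, 0.95)
  }
  removed <- dd$assignments[!(dd$assignments$member_id %in% reps$id), ]
  for (r in seq_len(nrow(removed))) {
    m <- seqs[ids == removed$member_id[r]]
    rp <- seqs[ids == removed$representative_id[r]]
    expect_gt(pairwise_identity(m, rp)$identity, 0.95)
  }
})

test_that("coverage grouping links substrings but not unrelated sequences", {
  set.seed(26)
  long <- paste(sample(AA_STANDARD, 200, replace = TRUE), collapse = "")
  sub <- substr(long, 45, 154)     # 110-residue exact substring
  other <- paste(sample(AA_STANDARD, 200, replace = TRUE), collapse = "")
  rec <- protein_records(c("long", "sub", "other"), c(long, sub, other))
  gr <- group_by_coverage(rec)
  expect_equal(gr$representative_id[gr$member_id == "sub"],
               gr$representative_id[gr$member_id == "long"])
  expect_false(gr$representative_id[gr$member_id == "other"] %in%
                 gr$representative_id[gr$member_id == "long"])
  # partition: every record in exactly one group
  expect_equal(sort(gr$member_id), sort(rec$id))
  # identical pair groups together
  twin <- protein_records(c("t1", "t2"), rep(strrep("MKLVHASDE", 25), 2))
  gt <- group_by_coverage(twin)
  expect_equal(length(unique(gt$representative_id)), 1L)
})
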