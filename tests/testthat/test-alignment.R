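test_that("hand-computed alignments score as expected", {
  # single mismatching pair: only level 1 differs in rank
  a <- pw_from_codes("1.2.1.1", "a")
  b <- pw_from_codes("2.2.1.1", "b")
  r <- align_pathways(a, b)
  expect_identical(r$raw_score, 0)
  expect_identical(r$similarity, 0)
  expect_identical(nrow(r$matches), 0L)

  # diagonal matching 0.75 + 0.25 + 1.0 is optimal
  q <- pw_from_codes(c("1.2.1.1", "4.1.1.1", "6.2.1.1"), "q")
  s <- pw_from_codes(c("1.2.1.2", "4.2.1.1", "6.2.1.1"), "s")
  r <- align_pathways(q, s)
  expect_identical(r$raw_score, 2)
  expect_equal(r$similarity, 2 / 3)
  expect_identical(r$matches$query_index, 1:3)
  expect_identical(r$matches$subject_index, 1:3)
  expect_identical(r$matches$sigma, c(0.75, 0.25, 1))

  # free gaps: a shared subsequence is fully credited, normalized by max length
  long <- pw_from_codes(c("2.3.1.1", "1.2.1.1", "4.1.1.1", "6.2.1.1"), "long")
  short <- pw_from_codes(c("1.2.1.1", "6.2.1.1"), "short")
  r <- align_pathways(short, long)
  expect_identical(r$raw_score, 2)
  expect_identical(r$similarity, 0.5)
})

test_that("self-alignment yields similarity exactly 1 at any length", {
  set.seed(7)
  for (len in c(1L, 3L, 8L)) {
    pw <- random_pathway(len, "self")
    r <- align_pathways(pw, pw)
    expect_identical(r$similarity, 1)
    expect_identical(r$raw_score, as.numeric(len))
    expect_identical(r$matches$sigma, rep(1, len))
  }
})

test_that("empty pathways cannot be aligned", {
  pw <- pw_from_codes("1.2.1.1", "a")
  fake <- pw
  fake$steps <- fake$steps[0, ]
  expect_error(align_pathways(pw, fake), class = "stpath_domain_error")
  expect_error(align_pathways(fake, pw), class = "stpath_domain_error")
})

test_that("DP equals exhaustive matching enumeration on random pairs", {
  set.seed(101)
  for (rep in 1:200) {
    p1 <- random_pathway(sample.int(6, 1), "p1")
    p2 <- random_pathway(sample.int(6, 1), "p2")
    r <- align_pathways(p1, p2)
    expect_identical(r$raw_score, brute_force_score(p1, p2))
    # reported matching is consistent with the score
    expect_identical(r$raw_score, sum(r$matches$sigma))
    if (nrow(r$matches) > 1) {
      expect_true(all(diff(r$matches$query_index) > 0))
      expect_true(all(diff(r$matches$subject_index) > 0))
    }
  }
})

test_that("similarity is symmetric, bounded, and 1 only for identical code sequences", {
  set.seed(55)
  for (rep in 1:50) {
    p1 <- random_pathway(sample.int(7, 1), "p1")
    p2 <- random_pathway(sample.int(7, 1), "p2")
    r12 <- align_pathways(p1, p2)
    r21 <- align_pathways(p2, p1)
    expect_identical(r12$similarity, r21$similarity)
    expect_gte(r12$similarity, 0)
    expect_lte(r12$similarity, 1)
    expect_lte(r12$raw_score, min(pathway_length(p1), pathway_length(p2)))
    if (r12$similarity == 1) {
      expect_identical(pathway_codes(p1), pathway_codes(p2))
    }
    if (identical(pathway_codes(p1), pathway_codes(p2))) {
      expect_identical(r12$similarity, 1)
    }
  }
})

test_that("appending an identical code to both pathways never lowers the raw score", {
  set.seed(77)
  for (rep in 1:30) {
    p1 <- random_pathway(sample.int(5, 1), "p1")
    p2 <- random_pathway(sample.int(5, 1), "p2")
    base <- align_pathways(p1, p2)$raw_score
    extra <- random_code()
    p1x <- pw_from_codes(c(pathway_codes(p1), extra), "p1x")
    p2x <- pw_from_codes(c(pathway_codes(p2), extra), "p2x")
    grown <- align_pathways(p1x, p2x)$raw_score
    expect_gte(grown, base)
    # the new pair can always be matched for +1
    expect_gte(grown, base + 1 - 1e-12)
  }
})

test_that("sharpening one code toward its aligned partner never lowers the score", {
  set.seed(99)
  for (rep in 1:30) {
    p1 <- random_pathway(sample.int(5, 1) + 1L, "p1")
    p2 <- random_pathway(pathway_length(p1), "p2")
    r <- align_pathways(p1, p2)
    if (nrow(r$matches) == 0) next
    m <- r$matches[sample.int(nrow(r$matches), 1L), ]
    # replace the subject code with the exact query code: strictly longer prefix
    codes2 <- pathway_codes(p2)
    codes2[m$subject_index] <- pathway_codes(p1)[m$query_index]
    r2 <- align_pathways(p1, pw_from_codes(codes2, "p2s"))
    expect_gte(r2$raw_score, r$raw_score)
  }
})

test_that("collection ranking sorts by similarity then subject id", {
  q <- pw_from_codes(c("1.2.1.1", "4.1.1.1", "6.2.1.1"), "query")
  copy <- pw_from_codes(pathway_codes(q), "copy")
  near <- pw_from_codes(c("1.2.1.2", "4.2.1.1", "6.2.1.1"), "near")
  far <- pw_from_codes(c("2.3.1.1", "3.2.1.1", "5.1.1.1"), "far")
  ranked <- rank_against_collection(q, list(far, near, copy))
  ids <- vapply(ranked, `[[`, character(1), "subject_id")
  expect_identical(ids, c("copy", "near", "far"))
  expect_identical(ranked[[1]]$similarity, 1)

  # ties broken lexicographically by subject id (0.75+0.25+1 vs 0.5+0.5+1)
  tie_b <- pw_from_codes(c("1.2.1.2", "4.2.1.1", "6.2.1.1"), "b_tie")
  tie_a <- pw_from_codes(c("1.2.2.1", "4.1.2.1", "6.2.1.1"), "a_tie")
  expect_identical(align_pathways(q, tie_a)$similarity,
                   align_pathways(q, tie_b)$similarity)
  ranked <- rank_against_collection(q, list(tie_b, tie_a))
  expect_identical(vapply(ranked, `[[`, character(1), "subject_id"),
                   c("a_tie", "b_tie"))

  # all-zero scores still return everything, ordered by id
  zeroq <- pw_from_codes("1.2.1.1", "z")
  subs <- list(pw_from_codes("2.3.1.1", "s2"), pw_from_codes("3.2.1.1", "s1"))
  ranked <- rank_against_collection(zeroq, subs)
  expect_identical(vapply(ranked, `[[`, character(1), "subject_id"),
                   c("s1", "s2"))
  expect_error(rank_against_collection(q, list()), class = "stpath_domain_error")
})

test_that("alignment results serialize to TSV with monotone match pairs", {
  q <- pw_from_codes(c("1.2.1.1", "4.1.1.1"), "q")
  s <- pw_from_codes(c("1.2.1.1", "4.1.1.1"), "s")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_tsv(rank_against_collection(q, list(s)), f)
  tab <- read.delim(f)
  expect_identical(names(tab),
                   c("query_id", "subject_id", "similarity", "raw_score",
                     "L1", "L2", "matches"))
  expect_identical(tab$matches, "1:1;2:2")
  expect_equal(tab$similarity, 1)
})
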