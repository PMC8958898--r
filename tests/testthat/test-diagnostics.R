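# Column classification, ranking, clade diagnosis and verification.

P2 <- diagnostic_params(min_clade_size_direct = 2L)

test_that("classify_column finds the direct character in TOY1", {
  cl <- classify_column(TOY1, c("s1", "s2"), 2L, P2)
  expect_equal(cl$kind, "direct")
  expect_equal(cl$ancestral, "T")
  expect_equal(cl$derived, "C")
  # invariant column: nothing to diagnose
  expect_equal(classify_column(TOY1, c("s1", "s2"), 1L, P2)$kind, "none")
})

test_that("state_only arises when the outside modal fails the threshold", {
  aln <- toy_alignment(c(s1 = "A", s2 = "A", s3 = "G", s4 = "T"),
                       locus_index("L1", 1L))
  cl <- classify_column(aln, c("s1", "s2"), 1L, P2)
  # outside is G/T: deviators 1 of 2 > 5%; no outsider carries A
  expect_equal(cl$kind, "state_only")
  expect_equal(cl$derived, "A")
  expect_true(is.na(cl$ancestral))
})

test_that("two-state clades give ambiguity-coded characters when allowed", {
  aln <- toy_alignment(c(s1 = "A", s2 = "G", s3 = "T", s4 = "T"),
                       locus_index("L1", 1L))
  p_amb <- diagnostic_params(min_clade_size_direct = 2L,
                             allow_ambiguity = TRUE)
  cl <- classify_column(aln, c("s1", "s2"), 1L, p_amb)
  expect_equal(cl$kind, "ambiguous")
  expect_equal(cl$ancestral, "T")
  expect_equal(cl$derived, "R")
  # without ambiguity the same column is none
  expect_equal(classify_column(aln, c("s1", "s2"), 1L, P2)$kind, "none")
})

test_that("an outsider carrying the clade state vetoes the character", {
  aln <- toy_alignment(c(s1 = "C", s2 = "C", s3 = "C", s4 = "T", s5 = "T",
                         s6 = "T", s7 = "T", s8 = "T", s9 = "T", s10 = "T",
                         s11 = "T", s12 = "T", s13 = "T", s14 = "T",
                         s15 = "T", s16 = "T", s17 = "T", s18 = "T",
                         s19 = "T", s20 = "T", s21 = "T", s22 = "T",
                         s23 = "C"),
                       locus_index("L1", 1L))
  # 20 outsiders, one of them carries C: 1/20 = 5% would pass the modal
  # threshold, but carrying the clade state is always disqualifying
  cl <- classify_column(aln, c("s1", "s2", "s3"), 1L, diagnostic_params())
  expect_equal(cl$kind, "none")
  # replace the carrier by a third state: modal threshold passes at 5%
  aln$matrix["s23", 1] <- "G"
  cl <- classify_column(aln, c("s1", "s2", "s3"), 1L, diagnostic_params())
  expect_equal(cl$kind, "direct")
})

test_that("missing members are tolerated; all-missing clades classify none", {
  aln <- toy_alignment(c(s1 = "C", s2 = "N", s3 = "T", s4 = "T"),
                       locus_index("L1", 1L))
  expect_equal(classify_column(aln, c("s1", "s2"), 1L, P2)$kind, "direct")
  aln$matrix["s1", 1] <- "-"
  expect_equal(classify_column(aln, c("s1", "s2"), 1L, P2)$kind, "none")
  expect_error(classify_column(aln, character(), 1L, P2), "empty")
})

test_that("ranking is missing-first, then depth, then locus/position", {
  ch <- taxodiag:::rbind_characters(
    diag_characters("cneB.1.1", 10L, "T", "C", n_missing = 1L,
                    min_depth = 50, mean_depth = 50),
    diag_characters("cneA.1.1", 5L, "T", "C", n_missing = 0L,
                    min_depth = 12, mean_depth = 20),
    diag_characters("cneA.1.1", 7L, "T", "C", n_missing = 0L,
                    min_depth = 40, mean_depth = 41),
    diag_characters("cneC.1.1", 2L, "T", "C", n_missing = 0L,
                    min_depth = 40, mean_depth = 41),
    diag_characters("cneA.1.1", 9L, "T", "C", n_missing = 0L,
                    min_depth = 40, mean_depth = 60)
  )
  r <- rank_characters(ch)
  expect_equal(format_character(r),
               c("cneA.1.1:T9C",    # 0 missing, min 40, mean 60
                 "cneA.1.1:T7C",    # 0 missing, min 40, mean 41, locus/pos
                 "cneC.1.1:T2C",
                 "cneA.1.1:T5C",    # 0 missing, min 12
                 "cneB.1.1:T10C"))  # 1 missing last
  # without coverage the order is deterministic on (locus, position)
  ch$min_depth <- NA_real_; ch$mean_depth <- NA_real_
  r <- rank_characters(ch)
  expect_equal(r$position[r$n_missing == 0L], c(5L, 7L, 9L, 2L))
})

test_that("diagnose_clade on TOY1 returns exactly the one character", {
  d <- diagnose_clade(TOY1, c("s1", "s2"), params = P2)
  expect_equal(format_character(d), "cne1.1.1:T2C")
  expect_error(diagnose_clade(TOY1, rownames(TOY1$matrix), params = P2),
               "outside")
  expect_error(diagnose_clade(TOY1, "s1", params = diagnostic_params()),
               "diagnose_small_clade")
  aln <- toy_alignment(c(s1 = "AC", s2 = "AC", s3 = "AC", s4 = "AC"))
  expect_warning(d <- diagnose_clade(aln, c("s1", "s2"), params = P2),
                 "no diagnostic character")
  expect_equal(nrow(d), 0L)
})

test_that("diagnose_clade agrees with the brute-force oracle", {
  set.seed(101)
  p <- diagnostic_params(min_clade_size_direct = 2L, k_report = 1000L)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    aln <- random_alignment(n, sample(10:50, 1))
    members <- sample(rownames(aln$matrix), pick1(2:(n - 2)))
    got <- suppressWarnings(diagnose_clade(aln, members, params = p))
    expect_identical(format_character(got), oracle_diagnose(aln, members))
  }
})

test_that("zero-noise planted characters are recovered exactly", {
  cfg <- default_sim_config(21, background_rate = 0, missing_max = 0)
  sim <- simulate_dataset(cfg)
  nuc <- extract_partition(sim$alignment, "nuclear")
  for (nm in c("A", "B", "C")) {
    d <- diagnose_clade(nuc, cfg$clades[[nm]])
    truth <- sim$truth$planted
    truth <- truth[truth$clade == nm & truth$locus_id != "COI", ]
    expect_setequal(format_character(d), format_character(truth))
  }
})

test_that("the sister-complement procedure mirrors the published structure", {
  # tree ((s1,(s2,s3)),(s4,s5)); column 1: s2,s3 = G, others A (sister char)
  # column 2: s1,s2,s3 = C, s4,s5 = T (parent char)
  tree <- ape::read.tree(text = "((s1,(s2,s3)),(s4,s5));")
  aln <- toy_alignment(c(s1 = "AC", s2 = "GC", s3 = "GC",
                         s4 = "AT", s5 = "AT"),
                       locus_index("cne5.1.1", 2L))
  d <- diagnose_small_clade(aln, tree, "s1", params = diagnostic_params())
  expect_setequal(format_character(d),
                  c("cne5.1.1:A1A (not G)", "cne5.1.1:T2C"))
  expect_equal(d$scope[match("cne5.1.1:T2C", format_character(d))], "parent")
  expect_equal(d$scope[match("cne5.1.1:A1A (not G)", format_character(d))],
               "sister_negated")
  # nothing to report when neighbourhood is featureless
  flat <- toy_alignment(c(s1 = "AA", s2 = "AA", s3 = "AA",
                          s4 = "AA", s5 = "AA"),
                        locus_index("cne5.1.1", 2L))
  expect_warning(d0 <- diagnose_small_clade(flat, tree, "s1"),
                 "no sister or parent")
  expect_equal(nrow(d0), 0L)
  # non-monophyletic member set is a structure error
  expect_error(diagnose_small_clade(aln, tree, c("s1", "s4")),
               "not monophyletic")
})

test_that("small-clade unions separate focal clades in zero-noise data", {
  cfg <- default_sim_config(31, background_rate = 0, missing_max = 0)
  sim <- simulate_dataset(cfg)
  nuc <- extract_partition(sim$alignment, "nuclear")
  for (nm in c("D", "E")) {
    members <- cfg$clades[[nm]]
    d <- diagnose_small_clade(nuc, sim$tree, members)
    expect_gt(nrow(d), 0L)
    sis <- taxodiag:::sister_tips(sim$tree, members)
    chk <- verify_characters(nuc, members, d, sister = sis,
                             parent = union(members, sis))
    expect_true(all(chk$holds))
    # the union separates: every non-member fails at least one character
    others <- setdiff(rownames(nuc$matrix), members)
    cols <- map_position(nuc$locus_index, d$locus_id, d$position) + 1L
    focal_state <- d$derived
    for (o in others) {
      matches <- nuc$matrix[o, cols] == focal_state
      expect_false(all(matches))
    }
  }
})

test_that("verify_characters accepts true characters and flags fabrications", {
  ch <- parse_character("cne1.1.1:T2C")
  out <- verify_characters(TOY1, c("s1", "s2"), ch)
  expect_true(out$holds)
  bad <- parse_character("cne1.1.1:A1C")
  out <- verify_characters(TOY1, c("s1", "s2"), bad)
  expect_false(out$holds)
  expect_match(out$offenders, "s1")
  expect_error(verify_characters(TOY1, c("s1", "s2"),
                                 parse_character("cneZ.1.1:A1C")),
               "unknown locus")
})
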