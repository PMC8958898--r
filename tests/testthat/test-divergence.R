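# Barcode extraction, p-distances, NJ trees, rooting and monophyly.

test_that("extract_barcode returns exactly 658 renumbered positions", {
  mat <- matrix(sample(c("A", "C", "G", "T"), 2 * 700, replace = TRUE), 2,
                dimnames = list(c("x", "y"), NULL))
  aln <- annotated_alignment(mat, locus_index("COI", 700L))
  bc <- extract_barcode(aln, 1L)
  expect_equal(ncol(bc$matrix), 658L)
  expect_equal(bc$locus_index$length, 658L)
  bc43 <- extract_barcode(aln, 43L)
  expect_identical(bc43$matrix[, 1L], aln$matrix[, 43L])
  expect_identical(bc43$matrix[, 658L], aln$matrix[, 700L])
  short <- annotated_alignment(mat[, 1:400], locus_index("COI", 400L))
  expect_error(extract_barcode(short, 1L), "range error")
  expect_error(extract_barcode(aln, 44L), "range error")
})

test_that("p_distance applies pairwise deletion", {
  expect_equal(p_distance(strsplit("ACGT", "")[[1]],
                          strsplit("ACGT", "")[[1]]),
               list(distance = 0, n_sites = 4L))
  expect_equal(p_distance(strsplit("ACGT", "")[[1]],
                          strsplit("ACGA", "")[[1]]),
               list(distance = 0.25, n_sites = 4L))
  expect_equal(p_distance(strsplit("ACNT", "")[[1]],
                          strsplit("ACGT", "")[[1]]),
               list(distance = 0, n_sites = 3L))
  # ambiguity codes are excluded like missing data
  expect_equal(p_distance(strsplit("ACRT", "")[[1]],
                          strsplit("ACGA", "")[[1]]),
               list(distance = 1 / 3, n_sites = 3L))
  expect_error(p_distance(c("A"), c("A", "C")), "length mismatch")
  expect_true(is.na(p_distance(c("N", "N"), c("A", "C"))$distance))
})

test_that("masking a site changes n_sites, never the mismatch count", {
  set.seed(5)
  a <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  b <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  full <- p_distance(a, b)
  i <- 7L
  was_mismatch <- a[i] != b[i]
  a[i] <- "N"
  masked <- p_distance(a, b)
  expect_equal(masked$n_sites, full$n_sites - 1L)
  expect_equal(round(masked$distance * masked$n_sites),
               round(full$distance * full$n_sites) - was_mismatch)
})

test_that("pairwise_matrix matches ape's raw pairwise-deletion distances", {
  set.seed(12)
  aln <- random_alignment(8, 120, p_missing = 0.08, p_ambig = 0)
  D <- pairwise_matrix(aln)
  bin <- ape::as.DNAbin(tolower(aln$matrix))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unname(D$d), unname(ref), tolerance = 1e-12)
  expect_true(isSymmetric(D$d))
  expect_true(all(diag(D$d) == 0))
  # an all-missing specimen is flagged NA, not zero
  aln$matrix["s01", ] <- "N"
  D <- pairwise_matrix(aln)
  expect_true(all(is.na(D$d["s01", -1])))
  expect_true(all(D$n_sites["s01", -1] == 0L))
})

test_that("clade divergence statistics are ordered and in percent", {
  labs <- c("a1", "a2", "b1", "b2")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["a1", "b1"] <- d["b1", "a1"] <- 0.06
  d["a1", "b2"] <- d["b2", "a1"] <- 0.08
  d["a2", "b1"] <- d["b1", "a2"] <- 0.07
  d["a2", "b2"] <- d["b2", "a2"] <- 0.09
  D <- structure(list(labels = labs, d = d,
                      n_sites = matrix(658L, 4, 4)),
                 class = "distance_matrix")
  A <- c("a1", "a2"); B <- c("b1", "b2")
  expect_equal(clade_divergence(D, A, B, "min"), 6)
  expect_equal(clade_divergence(D, A, B, "mean"), 7.5)
  expect_equal(clade_divergence(D, A, B, "max"), 9)
  expect_lte(clade_divergence(D, A, B, "min"),
             clade_divergence(D, A, B, "mean"))
  expect_lte(clade_divergence(D, A, B, "mean"),
             clade_divergence(D, A, B, "max"))
  expect_equal(clade_divergence(D, "a1", "b1", "mean"), 6)
  expect_error(clade_divergence(D, A, c("a1", "b1")), "disjoint")
})

test_that("nj_tree reconstructs the worked additive example", {
  labs <- c("a", "b", "c", "d")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # recovers the split ab|cd with internal edge 1
  ref <- ape::read.tree(text = "((a:1,b:2):1,c:3,d:4);")
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(ref)), 0)
  m <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(unname(m), unname(d), tolerance = 1e-9)
})

test_that("nj_tree matches ape::nj topologies on random additive inputs", {
  set.seed(202)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    d <- ape::cophenetic.phylo(tr)
    got <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(got), ape::unroot(tr)), 0)
    ref <- ape::nj(d)
    expect_equal(phangorn::RF.dist(ape::unroot(got), ape::unroot(ref)), 0)
  }
})

test_that("equal distances resolve deterministically via the tie-break", {
  labs <- c("c", "a", "d", "b")
  d <- matrix(1, 4, 4, dimnames = list(labs, labs)); diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d[1, 2] <- d[2, 1] <- NA
  expect_error(nj_tree(d), "undefined pair")
})

test_that("outgroup rooting places the root on the separating branch", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  rooted <- root_with_outgroup(tr, "d")
  expect_true(ape::is.rooted(rooted))
  expect_true(check_monophyly(rooted, c("a", "b", "c"))$is_monophyletic)
  expect_error(root_with_outgroup(tr, c("a", "c")), "not separable")
  expect_error(root_with_outgroup(tr, c("a", "b", "c", "d")), "all tips")
  expect_error(root_with_outgroup(tr, "zz"), "unknown outgroup")
})

test_that("check_monophyly matches MRCA set equality", {
  tr <- ape::read.tree(text = "((s1,s2),(s3,(s4,s5)));")
  m <- check_monophyly(tr, c("s4", "s5"))
  expect_true(m$is_monophyletic)
  expect_equal(m$mrca_size, 2L)
  expect_length(m$intruders, 0L)
  m <- check_monophyly(tr, c("s1", "s3"))
  expect_false(m$is_monophyletic)
  expect_equal(m$mrca_size, 5L)
  expect_setequal(m$intruders, c("s2", "s4", "s5"))
  m <- check_monophyly(tr, "s1")
  expect_true(m$is_monophyletic)
  expect_equal(m$mrca_size, 1L)
  expect_error(check_monophyly(tr, "zz"), "unknown tip")
})

test_that("monophyly agrees with a naive traversal on random trees", {
  set.seed(33)
  for (rep in 1:25) {
    n <- sample(5:20, 1)
    tr <- ape::rtree(n)
    tips <- sample(tr$tip.label, sample(1:n, 1))
    m <- check_monophyly(tr, tips)
    want <- oracle_mrca_tipset(tr, tips)
    expect_equal(m$is_monophyletic, setequal(want, tips))
    expect_equal(m$mrca_size, length(want))
    expect_setequal(m$intruders, setdiff(want, tips))
  }
})

test_that("simulated clades are monophyletic until an intruder is added", {
  cfg <- default_sim_config(3)
  sim <- simulate_dataset(cfg)
  tr <- sim$tree
  expect_true(check_monophyly(tr, cfg$clades$A)$is_monophyletic)
  expect_false(check_monophyly(tr, c(cfg$clades$A, "OG1"))$is_monophyletic)
})

test_that("distance matrices write as labelled TSV and PHYLIP", {
  set.seed(2)
  aln <- random_alignment(4, 50, p_missing = 0)
  D <- pairwise_matrix(aln)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(D, f)
  back <- utils::read.delim(f)
  expect_equal(back$label, D$labels)
  expect_equal(as.matrix(back[, -1]), D$d, ignore_attr = TRUE,
               tolerance = 1e-9)
  fp <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(D, fp, phylip = TRUE)
  expect_equal(as.integer(trimws(readLines(fp)[1])), 4L)
})
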