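#' Simulation configuration
#'
#' Describes a clade-structured dataset with planted synapomorphies: a tree
#' with branch lengths (expected substitutions per site per unit rate), a
#' locus table including a mitochondrial COI locus, planted position-level
#' synapomorphies on named clades, a background substitution rate, museomics
#' style per-specimen missing-data fractions, and a read-depth model.
#'
#' @param tree An [ape::phylo] tree with branch lengths; tips are specimens.
#' @param loci A [locus_index()]; must contain a `COI` locus of >= 658
#'   positions in the mito partition.
#' @param clades Named list of tip sets; planted characters refer to these
#'   names and each set must be monophyletic in `tree`.
#' @param planted Data frame with columns `clade`, `locus_id`, `local_pos`,
#'   `anc`, `der` — one planted substitution on the branch subtending each
#'   named clade. Positions must be unique per clade and `anc != der`.
#' @param background_rate Per-site substitution probability per unit branch
#'   length, in \[0,1\].
#' @param missing_fraction Scalar or per-specimen named vector of masked-cell
#'   fractions in \[0,1\].
#' @param depth_mean,depth_dispersion Read-depth model for covered cells:
#'   depth = 1 + NegBin(mu = depth_mean - 1, size = depth_dispersion), so
#'   covered cells always have depth >= 1 and masked cells depth 0.
#' @param seed Mandatory integer seed; identical seeds give bit-identical
#'   outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, loci, clades, planted,
                       background_rate = 0.01, missing_fraction = 0,
                       depth_mean = 25, depth_dispersion = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            inherits(loci, "locus_index"),
            background_rate >= 0, background_rate <= 1,
            all(missing_fraction >= 0), all(missing_fraction <= 1),
            depth_mean >= 1, depth_dispersion > 0)
  if (!"COI" %in% loci$locus_id ||
      loci$length[loci$locus_id == "COI"] < 658L) {
    stop("loci must include a COI locus of >= 658 positions")
  }
  stopifnot(is.data.frame(planted),
            all(c("clade", "locus_id", "local_pos", "anc", "der") %in%
                  names(planted)))
  if (any(planted$anc == planted$der)) stop("planted anc must differ from der")
  if (anyDuplicated(planted[, c("clade", "locus_id", "local_pos")])) {
    stop("planted positions must be unique per clade")
  }
  if (!all(planted$clade %in% names(clades))) {
    stop("planted clade absent from clade list")
  }
  for (nm in names(clades)) {
    if (!all(clades[[nm]] %in% tree$tip.label)) {
      stop("clade ", nm, " names tips absent from tree")
    }
  }
  # fail early if a planted position exceeds its locus
  invisible(map_position(loci, planted$locus_id, planted$local_pos))
  structure(list(tree = tree, loci = loci, clades = clades, planted = planted,
                 background_rate = background_rate,
                 missing_fraction = missing_fraction,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default study-style simulation conditions
#'
#' Twenty specimens on a fixed tree with unit branch lengths: nested
#' multi-specimen clades A (5), B (5) and C (4), a doubleton D (sister to C),
#' a singleton E1 (sister to the A+B+C+D clade) and a two-specimen outgroup —
#' the configuration a small genomic revision of a butterfly tribe works
#' with, including degraded-specimen missing data. Loci: 10 nuclear exons of
#' 500 bp (5 kb total) plus a 700 bp COI locus. Five nuclear synapomorphies
#' are planted on each of A, B and C; three on the C+D and A..D and A..E1
#' branches (feeding the small-clade complement diagnosis of D and E1); three
#' COI characters on each of A, B and C. Per-specimen missing fractions are
#' drawn uniformly from \[0, missing_max\] under the seed.
#'
#' @param seed Integer seed.
#' @param background_rate Background substitution probability per site per
#'   unit branch length (default 0.01).
#' @param missing_max Upper bound of per-specimen missing fractions
#'   (default 0.2; 0 disables masking).
#' @return A `sim_config`.
#' @export
default_sim_config <- function(seed, background_rate = 0.01,
                               missing_max = 0.2) {
  nwk <- paste0(
    "(((((A1:1,(A2:1,(A3:1,(A4:1,A5:1):1):1):1):1,",
    "(B1:1,(B2:1,(B3:1,(B4:1,B5:1):1):1):1):1):1,",
    "((C1:1,(C2:1,(C3:1,C4:1):1):1):1,(D1:1,D2:1):1):1):1,E1:2):1,",
    "(OG1:1,(OG2:1,OG3:1):1):1);"
  )
  tree <- ape::read.tree(text = nwk)
  loci <- locus_index(
    c(sprintf("cne%d.%d.%d", c(101, 101, 230, 230, 417, 902, 1547, 1547,
                               2210, 3308),
      c(1, 1, 2, 5, 1, 3, 14, 14, 1, 2), c(1, 2, 1, 1, 3, 1, 1, 2, 1, 4)),
      "COI"),
    c(rep(500L, 10L), 700L)
  )
  A <- paste0("A", 1:5); B <- paste0("B", 1:5)
  C <- paste0("C", 1:4); D <- paste0("D", 1:2)
  clades <- list(A = A, B = B, C = C, D = D, E = "E1",
                 CD = c(C, D), ABCD = c(A, B, C, D),
                 ABCDE = c(A, B, C, D, "E1"), OG = c("OG1", "OG2", "OG3"))
  nuc <- loci$locus_id[loci$partition == "nuclear"]
  plant <- function(clade, locus, pos, anc, der) {
    data.frame(clade = clade, locus_id = locus, local_pos = pos,
               anc = anc, der = der, stringsAsFactors = FALSE)
  }
  planted <- rbind(
    plant("A", nuc[c(1, 2, 4, 6, 9)], c(50, 120, 333, 17, 481), "T", "C"),
    plant("B", nuc[c(1, 3, 5, 7, 10)], c(260, 44, 402, 139, 77), "A", "G"),
    plant("C", nuc[c(2, 4, 6, 8, 9)], c(310, 55, 218, 460, 12), "G", "A"),
    plant("CD", nuc[c(3, 5, 7)], c(371, 90, 251), "C", "T"),
    plant("ABCD", nuc[c(1, 8, 10)], c(430, 199, 365), "A", "T"),
    plant("ABCDE", nuc[c(2, 6, 9)], c(88, 140, 272), "T", "A"),
    plant("A", "COI", c(22, 97, 268), "A", "T"),
    plant("B", "COI", c(38, 283, 506), "G", "A"),
    plant("C", "COI", c(154, 421, 592), "T", "C")
  )
  set.seed(seed)
  frac <- if (missing_max > 0) {
    stats::setNames(stats::runif(length(tree$tip.label), 0, missing_max),
                    tree$tip.label)
  } else 0
  sim_config(tree, loci, clades, planted,
             background_rate = background_rate, missing_fraction = frac,
             seed = seed)
}

#' Simulate an annotated alignment with planted synapomorphies
#'
#' Draws the root sequence uniformly per site, applies background
#' substitutions along each branch (per-site Bernoulli with probability
#' `background_rate * branch_length`, uniform target among the other three
#' bases), then applies each planted substitution deterministically on the
#' branch subtending its clade. Planted truth is exact: planted columns are
#' exempt from background substitution everywhere, and the missing mask never
#' blanks every member of a clade at one of its planted columns (one member
#' is kept observed). Masked cells are `N` with depth 0; covered cells draw
#' depth from the shifted negative-binomial model.
#'
#' @param cfg A [sim_config()].
#' @return List with `alignment` ([annotated_alignment()]), `coverage`
#'   (integer depth matrix), `tree`, and `truth` (list: `planted` as a
#'   [diag_characters()] frame plus `clade` column, `n_background_events`,
#'   `seed`, `config` echo).
#' @export
simulate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  tree <- ape::reorder.phylo(cfg$tree, "cladewise")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nsites <- n_columns(cfg$loci)

  planted_col <- map_position(cfg$loci, cfg$planted$locus_id,
                              cfg$planted$local_pos) + 1L
  planted_node <- vapply(cfg$planted$clade, function(nm) {
    mrca_node(tree, cfg$clades[[nm]])
  }, integer(1))
  for (k in seq_along(planted_node)) {
    nm <- cfg$planted$clade[k]
    if (!setequal(tips_under(tree, planted_node[k]), cfg$clades[[nm]])) {
      stop("planted clade ", nm, " is not monophyletic in the tree")
    }
  }

  root <- ntip + 1L
  seqs <- matrix(NA_character_, nnode, nsites)
  seqs[root, ] <- sample(BASES, nsites, replace = TRUE)
  seqs[root, planted_col] <- cfg$planted$anc   # ancestral state is known

  free <- setdiff(seq_len(nsites), unique(planted_col))
  n_events <- 0L
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; chd <- tree$edge[e, 2L]
    s <- seqs[par, ]
    p <- cfg$background_rate * tree$edge.length[e]
    if (p > 0 && length(free)) {
      mut <- free[stats::runif(length(free)) < p]
      if (length(mut)) {
        n_events <- n_events + length(mut)
        s[mut] <- vapply(s[mut], function(b) sample(setdiff(BASES, b), 1L),
                         character(1))
      }
    }
    hit <- which(planted_node == chd)
    if (length(hit)) s[planted_col[hit]] <- cfg$planted$der[hit]
    seqs[chd, ] <- s
  }

  mat <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(mat) <- tree$tip.label

  # museomics-style missing mask, per specimen
  frac <- cfg$missing_fraction
  if (length(frac) == 1L && is.null(names(frac))) {
    frac <- stats::setNames(rep(frac, ntip), tree$tip.label)
  }
  masked <- matrix(FALSE, ntip, nsites, dimnames = list(tree$tip.label, NULL))
  for (id in tree$tip.label) {
    f <- frac[[id]]
    if (f > 0) {
      k <- round(f * nsites)
      if (k > 0) masked[id, sample.int(nsites, k)] <- TRUE
    }
  }
  # keep every planted character observable in its clade
  for (k in seq_len(nrow(cfg$planted))) {
    memb <- cfg$clades[[cfg$planted$clade[k]]]
    j <- planted_col[k]
    if (all(masked[memb, j])) {
      keep <- memb[sample.int(length(memb), 1L)]
      masked[keep, j] <- FALSE
    }
  }
  mat[masked] <- "N"

  depth <- matrix(0L, ntip, nsites, dimnames = list(tree$tip.label, NULL))
  ncov <- sum(!masked)
  depth[!masked] <- 1L + stats::rnbinom(ncov, size = cfg$depth_dispersion,
                                        mu = cfg$depth_mean - 1)

  aln <- annotated_alignment(mat, cfg$loci)
  truth_chars <- diag_characters(
    locus_id = cfg$planted$locus_id, position = cfg$planted$local_pos,
    ancestral = cfg$planted$anc, derived = cfg$planted$der, kind = "direct",
    scope = "focal",
    n_missing = vapply(seq_len(nrow(cfg$planted)), function(k) {
      sum(masked[cfg$clades[[cfg$planted$clade[k]]], planted_col[k]])
    }, integer(1))
  )
  truth_chars$clade <- cfg$planted$clade

  list(alignment = aln, coverage = depth, tree = tree,
       truth = list(planted = truth_chars, n_background_events = n_events,
                    seed = cfg$seed, config = cfg))
}

#' Write simulation truth as JSON
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(
    seed = truth$seed,
    n_background_events = truth$n_background_events,
    planted = data.frame(clade = truth$planted$clade,
                         character = format_character(truth$planted))
  ), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
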