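#' Extract the standard COI barcode region
#'
#' Cuts the standard 658-position barcode window out of a mitochondrial
#' alignment's COI locus and renumbers its columns 1..658 (the coordinate
#' system used by COI diagnostic characters).
#'
#' @param mito_aln An [annotated_alignment()] containing a `COI` locus.
#' @param barcode_start 1-based start of the barcode within the COI locus.
#' @return An [annotated_alignment()] with a single 658-column `COI` locus.
#' @export
extract_barcode <- function(mito_aln, barcode_start = 1L) {
  BARCODE_LEN <- 658L
  coi <- extract_locus(mito_aln, "COI")
  end <- barcode_start + BARCODE_LEN - 1L
  if (barcode_start < 1L || end > ncol(coi$matrix)) {
    stop("range error: barcode window [", barcode_start, ", ", end,
         "] exceeds COI locus of length ", ncol(coi$matrix))
  }
  idx <- locus_index("COI", BARCODE_LEN, partition = "mito")
  annotated_alignment(coi$matrix[, barcode_start:end, drop = FALSE], idx)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Pairwise deletion: positions where either sequence is missing (`N`, `-`)
#' or carries an ambiguity code are excluded; the distance is the fraction of
#' mismatches among the remaining compared sites. Undefined (distance `NA`)
#' when no site is comparable.
#'
#' @param a,b Character vectors (alignment rows) of equal length.
#' @return List with `distance` (fraction in \[0,1\] or `NA`) and `n_sites`.
#' @export
p_distance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  ok <- is_data_symbol(a) & is_data_symbol(b)
  n <- sum(ok)
  list(distance = if (n > 0L) sum(a[ok] != b[ok]) / n else NA_real_,
       n_sites = n)
}

#' All pairwise p-distances of an alignment
#'
#' @param aln An [annotated_alignment()] with at least two specimens.
#' @return A `distance_matrix`: list with `labels`, symmetric `d` (p-distance,
#'   `NA` where no sites compare) and symmetric integer `n_sites`. Undefined
#'   pairs are flagged by `NA`, never silently zeroed.
#' @export
pairwise_matrix <- function(aln) {
  ids <- specimen_ids(aln)
  n <- length(ids)
  if (n < 2L) stop("need at least two specimens")
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  ns <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(ns) <- ncol(aln$matrix)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pd <- p_distance(aln$matrix[i, ], aln$matrix[j, ])
    d[i, j] <- d[j, i] <- pd$distance
    ns[i, j] <- ns[j, i] <- pd$n_sites
  }
  structure(list(labels = ids, d = d, n_sites = ns),
            class = "distance_matrix")
}

#' Divergence between two clades
#'
#' @param D A `distance_matrix` from [pairwise_matrix()].
#' @param A,B Disjoint non-empty label sets.
#' @param stat `"min"`, `"mean"` or `"max"` over defined cross pairs.
#' @return Percent divergence (p-distance x 100).
#' @export
clade_divergence <- function(D, A, B, stat = c("mean", "min", "max")) {
  stat <- match.arg(stat)
  if (!length(A) || !length(B)) stop("empty clade")
  if (length(intersect(A, B))) stop("clades must be disjoint")
  if (!all(c(A, B) %in% D$labels)) stop("unknown label")
  x <- D$d[A, B, drop = FALSE]
  x <- x[!is.na(x)]
  if (!length(x)) stop("all cross pairs undefined")
  100 * switch(stat, min = min(x), mean = mean(x), max = max(x))
}

#' Neighbor-joining tree with a deterministic tie-break
#'
#' Standard neighbor joining over a complete distance matrix. When several
#' pairs minimise the Q criterion the pair whose subtrees contain the
#' lexicographically least tip labels is joined, so the output is identical
#' across runs. Negative branch lengths are clamped to zero with a warning.
#' On distances additive on a tree, the true unrooted topology is recovered.
#'
#' @param D A `distance_matrix` or plain symmetric numeric matrix with
#'   dimnames; all off-diagonal entries must be defined. At least 3 taxa.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  d <- if (inherits(D, "distance_matrix")) D$d else D
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(is.na(d[upper.tri(d)]))) stop("undefined pair in distance matrix")

  frag <- labels                  # newick fragment per active node
  rep_tip <- labels               # lexicographically least tip per subtree
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }

  while (n > 3L) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(rep_tip[cand[k, 1L]], rep_tip[cand[k, 2L]]))
      paste(pr, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]

    bi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- clamp(d[i, j] - bi)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    new_rep <- min(rep_tip[i], rep_tip[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2

    keep <- setdiff(seq_len(n), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_tip <- c(rep_tip[keep], new_rep)
    n <- n - 1L
  }
  # terminal trifurcation with closed-form edge lengths
  v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], v1, frag[2], v2, frag[3], v3)
  if (clamped) warning("negative branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Root a tree with an outgroup
#'
#' Places the root on the branch separating the outgroup tips from the rest
#' (as a genus-level study roots its tree with a distant outgroup species).
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Tip labels; must form one side of a split of the unrooted
#'   tree and not be all tips.
#' @return A rooted [ape::phylo] tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  if (!all(outgroup %in% tree$tip.label)) stop("unknown outgroup tip")
  if (length(outgroup) >= length(tree$tip.label)) {
    stop("outgroup cannot contain all tips")
  }
  if (length(outgroup) > 1L &&
      !ape::is.monophyletic(tree, outgroup, reroot = TRUE)) {
    stop("outgroup not separable: no branch splits it from the rest")
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Test a tip set for monophyly
#'
#' A set is monophyletic on a rooted tree iff the tip set of its most recent
#' common ancestor equals the set itself (singletons are trivially
#' monophyletic).
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param tips Tip labels (subset of the tree's tips).
#' @return List with `is_monophyletic`, `mrca_size` (tip count under the
#'   MRCA) and `intruders` (MRCA tips not in `tips`).
#' @export
check_monophyly <- function(tree, tips) {
  if (!all(tips %in% tree$tip.label)) {
    stop("unknown tip: ", paste(setdiff(tips, tree$tip.label), collapse = ", "))
  }
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  node <- mrca_node(tree, tips)
  under <- tips_under(tree, node)
  list(is_monophyletic = setequal(under, tips),
       mrca_size = length(under),
       intruders = setdiff(under, tips))
}

#' Write a distance matrix as TSV
#'
#' @param D A `distance_matrix`.
#' @param path Output path. A labelled square matrix (first column = label);
#'   `phylip = TRUE` writes the PHYLIP square format (taxon count header).
#' @param phylip Logical.
#' @export
write_distance_matrix <- function(D, path, phylip = FALSE) {
  m <- D$d
  if (phylip) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(m)), con)
    for (i in seq_len(nrow(m))) {
      writeLines(paste(c(formatC(D$labels[i], width = -10),
                         sprintf("%.6f", m[i, ])), collapse = " "), con)
    }
  } else {
    utils::write.table(data.frame(label = D$labels, m, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(D)
}
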