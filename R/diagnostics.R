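#' Parameters for diagnostic-character discovery
#'
#' @param max_outside_mismatch_fraction Fraction of non-missing outside
#'   specimens allowed to deviate from the modal outside state ("mostly
#'   invariant" outside); deviators may never carry the clade state. Default
#'   0.05.
#' @param min_clade_size_direct Clades smaller than this are diagnosed via the
#'   sister-clade complement procedure ([diagnose_small_clade()]). Default 3,
#'   i.e. clades of one or two specimens get the complement treatment.
#' @param k_report Number of top-ranked characters reported per clade/scope.
#'   Default 5.
#' @param allow_ambiguity Allow two-state (IUPAC-coded) derived states where a
#'   clade is polymorphic. Default `FALSE`; barcode diagnosis enables it,
#'   matching practice where ambiguity-coded characters appear in COI lists.
#' @param formula_max_terms,formula_max_literals Bounds of the disjunctive
#'   formula search in [find_barcode_formula()]. Defaults 2 and 2.
#' @return A `diagnostic_params` list.
#' @export
diagnostic_params <- function(max_outside_mismatch_fraction = 0.05,
                              min_clade_size_direct = 3L,
                              k_report = 5L,
                              allow_ambiguity = FALSE,
                              formula_max_terms = 2L,
                              formula_max_literals = 2L) {
  stopifnot(max_outside_mismatch_fraction >= 0,
            max_outside_mismatch_fraction < 1,
            min_clade_size_direct >= 1L, k_report >= 1L,
            formula_max_terms >= 1L, formula_max_literals >= 1L)
  structure(list(
    max_outside_mismatch_fraction = max_outside_mismatch_fraction,
    min_clade_size_direct = as.integer(min_clade_size_direct),
    k_report = as.integer(k_report),
    allow_ambiguity = isTRUE(allow_ambiguity),
    formula_max_terms = as.integer(formula_max_terms),
    formula_max_literals = as.integer(formula_max_literals)
  ), class = "diagnostic_params")
}

# Count A/C/G/T per column for a sub-matrix (4 x ncol). Symbols other than
# the four bases (N, -, input ambiguity codes) carry no data.
base_counts <- function(mat) {
  out <- vapply(BASES, function(b) colSums(mat == b), numeric(ncol(mat)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L, dimnames = list(NULL, BASES))
  out   # |columns| x 4
}

#' Classify one alignment column against a clade
#'
#' Implements the synapomorphy test for a single column. Let the focal
#' members' non-missing states and the outside specimens' non-missing states
#' be tallied (only A/C/G/T count as data). With `f` the allowed outside
#' mismatch fraction:
#' \itemize{
#' \item `direct(anc, der)`: all members with data share one state `der`; the
#'   outside specimens have a modal state `anc != der`; outsiders deviating
#'   from `anc` number at most `f` of non-missing outsiders; and no outsider
#'   carries `der` at all.
#' \item `state_only(der)`: members invariant at `der`, no outsider carries
#'   `der`, but no outside modal state passes the `f` threshold (the ancestral
#'   state is unclear).
#' \item `ambiguous(anc, code)`: only when ambiguity is allowed — members show
#'   exactly two states, no outsider carries either, and the outside modal
#'   state passes the threshold; `code` is the two-fold IUPAC union.
#' \item `none` otherwise, including when no member or no outsider has data
#'   at the column (nothing to compare).
#' }
#' Modal-state ties are broken towards the alphabetically first base.
#'
#' @param aln An [annotated_alignment()].
#' @param members Non-empty proper subset of specimen ids.
#' @param column Global column, 1-based as an R matrix index.
#' @param params [diagnostic_params()].
#' @param outside Comparison set; defaults to all other specimens.
#' @return A list with `kind` (one of `direct`, `state_only`, `ambiguous`,
#'   `none`), `ancestral` and `derived`.
#' @export
classify_column <- function(aln, members, column,
                            params = diagnostic_params(), outside = NULL) {
  cands <- candidate_characters(aln, members, params = params,
                                columns = column, outside = outside,
                                allow_ambiguity = params$allow_ambiguity)
  if (!nrow(cands)) {
    return(list(kind = "none", ancestral = NA_character_,
                derived = NA_character_))
  }
  kind <- if (cands$derived %in% BASES) cands$kind else "ambiguous"
  list(kind = kind, ancestral = cands$ancestral, derived = cands$derived)
}

# Vectorised scan over columns; returns a diag_characters frame of all
# columns whose classification is not `none`, with coverage stats attached.
candidate_characters <- function(aln, members, params = diagnostic_params(),
                                 cov = NULL, columns = NULL, outside = NULL,
                                 allow_ambiguity = params$allow_ambiguity) {
  ids <- specimen_ids(aln)
  if (!length(members)) stop("empty member set")
  if (!all(members %in% ids)) {
    stop("unknown specimen(s): ", paste(setdiff(members, ids), collapse = ", "))
  }
  if (is.null(outside)) outside <- setdiff(ids, members)
  if (!length(outside)) stop("member set must be a proper subset of specimens")
  if (length(intersect(members, outside))) stop("members overlap outside set")
  if (is.null(columns)) columns <- seq_len(ncol(aln$matrix))

  mm <- aln$matrix[members, columns, drop = FALSE]
  oo <- aln$matrix[outside, columns, drop = FALSE]
  cm <- base_counts(mm)                     # |columns| x 4
  co <- base_counts(oo)
  nm <- rowSums(cm)                         # members with data
  no <- rowSums(co)                         # outsiders with data
  nstates_m <- rowSums(cm > 0)
  f <- params$max_outside_mismatch_fraction

  mx <- pmax(co[, 1L], co[, 2L], co[, 3L], co[, 4L])
  modal <- max.col(co, ties.method = "first")   # alphabetically first on ties
  dev_ok <- (no - mx) <= f * no

  # single member state (valid only where nstates_m == 1)
  s_idx <- max.col(cm, ties.method = "first")
  o_has_s <- co[cbind(seq_along(columns), s_idx)] > 0

  single <- nstates_m == 1L & nm > 0L & no > 0L & !o_has_s
  direct <- single & dev_ok
  state_only <- single & !dev_ok

  kind <- rep(NA_character_, length(columns))
  anc <- rep(NA_character_, length(columns))
  der <- rep(NA_character_, length(columns))
  kind[direct] <- "direct"
  anc[direct] <- BASES[modal[direct]]
  der[direct | state_only] <- BASES[s_idx[direct | state_only]]
  kind[state_only] <- "state_only"

  if (allow_ambiguity) {
    two <- which(nstates_m == 2L & nm > 0L & no > 0L & dev_ok)
    for (j in two) {
      ss <- BASES[cm[j, ] > 0]
      if (co[j, match(ss[1], BASES)] == 0 && co[j, match(ss[2], BASES)] == 0) {
        kind[j] <- "direct"                 # notation-wise a direct character
        anc[j] <- BASES[modal[j]]
        der[j] <- iupac_pair(ss[1], ss[2])
      }
    }
  }

  hit <- which(!is.na(kind))
  if (!length(hit)) return(empty_characters())
  lp <- unmap_position(aln$locus_index, columns[hit] - 1L)

  min_d <- mean_d <- rep(NA_real_, length(hit))
  if (!is.null(cov)) {
    for (k in seq_along(hit)) {
      j <- columns[hit[k]]
      d <- cov[members, j]
      d <- d[d > 0L]                        # members with data at the column
      if (length(d)) { min_d[k] <- min(d); mean_d[k] <- mean(d) }
    }
  }
  diag_characters(
    locus_id = lp$locus_id, position = lp$local_pos,
    ancestral = anc[hit], derived = der[hit], kind = kind[hit],
    scope = "focal", n_missing = length(members) - nm[hit],
    min_depth = min_d, mean_depth = mean_d
  )
}

#' Rank candidate diagnostic characters
#'
#' Characters are ordered by ascending number of clade members with missing
#' data, then by descending minimum read depth, then descending mean depth
#' (better-covered positions first), with `(locus_id, position)` as the final
#' deterministic tie-break. Without coverage the depth keys are equal.
#'
#' @param cands A [diag_characters()] frame for one clade.
#' @return The same frame, reordered.
#' @export
rank_characters <- function(cands) {
  if (!nrow(cands)) return(cands)
  mind <- ifelse(is.na(cands$min_depth), 0, cands$min_depth)
  meand <- ifelse(is.na(cands$mean_depth), 0, cands$mean_depth)
  o <- order(cands$n_missing, -mind, -meand, cands$locus_id, cands$position,
             method = "radix")
  out <- cands[o, ]
  rownames(out) <- NULL
  out
}

#' Diagnose a clade with several specimens
#'
#' Scans every alignment column, keeps those classified as diagnostic for the
#' clade (see [classify_column()]), ranks them by missing data and coverage
#' ([rank_characters()]) and returns the top `k_report`.
#'
#' @param aln An [annotated_alignment()].
#' @param members Clade member ids; at least `min_clade_size_direct` of them
#'   (smaller clades go through [diagnose_small_clade()]).
#' @param cov Optional depth matrix paired with `aln`.
#' @param params [diagnostic_params()].
#' @param outside Comparison set; defaults to all other specimens.
#' @return A [diag_characters()] frame (possibly empty, with a warning).
#' @export
diagnose_clade <- function(aln, members, cov = NULL,
                           params = diagnostic_params(), outside = NULL) {
  if (length(members) < params$min_clade_size_direct) {
    stop("clade of ", length(members), " specimen(s): use diagnose_small_clade()")
  }
  if (length(members) >= length(specimen_ids(aln))) {
    stop("member set must leave a non-empty outside set")
  }
  cands <- candidate_characters(aln, members, params, cov, outside = outside)
  if (!nrow(cands)) {
    warning("no diagnostic character found for clade")
    return(cands)
  }
  ranked <- rank_characters(cands)
  utils::head(ranked, params$k_report)
}

# Tip ids under a node (the node's clade), via the tree's edge table.
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[phangorn::Descendants(tree, node, type = "tips")[[1]]]
}

# MRCA node of a tip set (the tip itself for singletons).
mrca_node <- function(tree, tips) {
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

# Sister clade of the subtree containing exactly `members`; errors if the
# members are not monophyletic.
sister_tips <- function(tree, members) {
  node <- mrca_node(tree, members)
  if (!setequal(tips_under(tree, node), members)) {
    stop("structure error: members are not monophyletic in the tree")
  }
  parent <- tree$edge[tree$edge[, 2L] == node, 1L]
  if (!length(parent)) stop("structure error: clade has no sister (root)")
  sibs <- tree$edge[tree$edge[, 1L] == parent, 2L]
  sibs <- setdiff(sibs, node)
  unlist(lapply(sibs, tips_under, tree = tree))
}

#' Diagnose a clade of one or two specimens via the sister complement
#'
#' Small clades cannot show convincing synapomorphies of their own (a private
#' state may be a random change or a sequencing error), so the diagnosis is
#' assembled from the neighbourhood: (a) direct synapomorphies of the sister
#' clade, restated as "retained" characters — the focal clade keeps the
#' ancestral state, annotated `(not X)` where `X` is the sister's derived
#' state; and (b) direct synapomorphies of the parent clade (members plus
#' sister) against everything else. The union diagnoses the taxon.
#'
#' @param aln An [annotated_alignment()].
#' @param tree Rooted tree containing all specimens; `members` must be
#'   monophyletic in it.
#' @param members One or two specimen ids.
#' @param cov Optional depth matrix.
#' @param params [diagnostic_params()]; each scope is ranked and truncated to
#'   `k_report` separately.
#' @return A [diag_characters()] frame with scopes `sister_negated` and
#'   `parent` (empty, with a warning, if neither scope yields characters).
#' @export
diagnose_small_clade <- function(aln, tree, members, cov = NULL,
                                 params = diagnostic_params()) {
  sis <- sister_tips(tree, members)
  ids <- specimen_ids(aln)
  if (!all(c(members, sis) %in% ids)) stop("tree tips missing from alignment")

  # (a) sister synapomorphies -> retained_not characters of the focal clade
  sis_cands <- candidate_characters(aln, sis, params, cov)
  sis_cands <- sis_cands[sis_cands$kind == "direct" &
                           sis_cands$derived %in% BASES, ]
  negated <- empty_characters()
  if (nrow(sis_cands)) {
    col <- map_position(aln$locus_index, sis_cands$locus_id,
                        sis_cands$position) + 1L
    keep <- logical(nrow(sis_cands))
    state <- character(nrow(sis_cands))
    nmiss <- integer(nrow(sis_cands))
    for (k in seq_len(nrow(sis_cands))) {
      foc <- aln$matrix[members, col[k]]
      foc_data <- foc[is_data_symbol(foc)]
      u <- unique(foc_data)
      # focal members must agree on a retained state distinct from the
      # sister's derived state
      if (length(u) == 1L && u != sis_cands$derived[k]) {
        keep[k] <- TRUE
        state[k] <- u
        nmiss[k] <- length(members) - length(foc_data)
      }
    }
    if (any(keep)) {
      sk <- sis_cands[keep, ]
      negated <- diag_characters(
        locus_id = sk$locus_id, position = sk$position,
        ancestral = state[keep], derived = state[keep],
        kind = "retained_not", excluded_state = sk$derived,
        scope = "sister_negated", n_missing = nmiss[keep],
        min_depth = member_depth(cov, members, col[keep], min),
        mean_depth = member_depth(cov, members, col[keep], mean)
      )
      negated <- utils::head(rank_characters(negated), params$k_report)
    }
  }

  # (b) parent-clade synapomorphies (members + sister vs the rest)
  parent_set <- union(members, sis)
  parent <- empty_characters()
  if (length(parent_set) < length(ids)) {
    pc <- candidate_characters(aln, parent_set, params, cov)
    pc <- pc[pc$kind == "direct" & pc$derived %in% BASES, ]
    if (nrow(pc)) {
      pc$scope <- "parent"
      parent <- utils::head(rank_characters(pc), params$k_report)
    }
  }

  out <- rbind_characters(parent, negated)
  if (!nrow(out)) warning("no sister or parent characters found for small clade")
  out
}

# depth summary over clade members with data at given columns (NA without cov)
member_depth <- function(cov, members, cols, fun) {
  if (is.null(cov)) return(rep(NA_real_, length(cols)))
  vapply(cols, function(j) {
    d <- cov[members, j]
    d <- d[d > 0L]
    if (length(d)) fun(d) else NA_real_
  }, numeric(1))
}

#' Verify diagnostic characters against an alignment
#'
#' Re-evaluates emitted characters on the data: a `direct` (or `state_only`)
#' character holds iff every clade member with data carries the derived state
#' (any base of a two-fold code) and no outside specimen with data carries it;
#' a `retained_not` character holds iff every member with data carries the
#' retained state and, when the sister set is supplied, no sister member
#' carries it.
#'
#' @param aln An [annotated_alignment()].
#' @param members Clade member ids.
#' @param characters A [diag_characters()] frame.
#' @param sister Optional sister-clade ids, used for `retained_not` rows.
#' @param parent Optional parent-clade ids (members plus sister); rows with
#'   `scope == "parent"` describe a synapomorphy of the parent clade and are
#'   evaluated against it.
#' @return The input frame with logical column `holds` and a character column
#'   `offenders` naming violating specimens (comma-separated).
#' @export
verify_characters <- function(aln, members, characters, sister = NULL,
                              parent = NULL) {
  if (!nrow(characters)) {
    characters$holds <- logical(); characters$offenders <- character()
    return(characters)
  }
  cols <- map_position(aln$locus_index, characters$locus_id,
                       characters$position) + 1L
  ids <- specimen_ids(aln)
  holds <- logical(nrow(characters))
  off <- character(nrow(characters))
  for (k in seq_len(nrow(characters))) {
    st <- iupac_expand(characters$derived[k])
    grp <- if (characters$scope[k] == "parent" && !is.null(parent)) {
      parent
    } else members
    memb <- aln$matrix[grp, cols[k]]
    m_data <- is_data_symbol(memb)
    bad_m <- grp[m_data & !(memb %in% st)]
    if (characters$kind[k] == "retained_not") {
      bad_o <- character()
      if (!is.null(sister)) {
        sv <- aln$matrix[sister, cols[k]]
        bad_o <- sister[is_data_symbol(sv) & sv %in% st]
      }
    } else {
      outside <- setdiff(ids, grp)
      ov <- aln$matrix[outside, cols[k]]
      bad_o <- outside[is_data_symbol(ov) & ov %in% st]
    }
    holds[k] <- !length(bad_m) && !length(bad_o) && any(m_data)
    off[k] <- paste(c(bad_m, bad_o), collapse = ",")
  }
  characters$holds <- holds
  characters$offenders <- off
  characters
}
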