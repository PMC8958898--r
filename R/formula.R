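#' Disjunctive barcode formulas
#'
#' A character formula is a small disjunction of conjunctions ("DNF") of
#' position/state literals over the COI barcode, used when no single position
#' separates a polymorphic clade — e.g. `G506A or G38A & T283A`. A specimen
#' satisfies a literal when it carries that base at that position; it
#' satisfies a term when it has data at all of the term's positions and
#' matches every literal. The formula separates a clade when every member
#' with data at at least one complete term satisfies some term, at least one
#' member satisfies the formula, and no outside specimen satisfies any term.
#'
#' @name character_formula
NULL

new_formula <- function(terms, clade = NA_character_) {
  structure(list(terms = terms, clade = clade), class = "character_formula")
}

formula_n_literals <- function(f) {
  if (is.null(f)) 0L else sum(vapply(f$terms, nrow, integer(1)))
}

#' Render a formula in diagnosis notation
#'
#' Literals within a term are joined with `" & "`, terms with `" or "`. Each
#' literal is written as an ancestral-position-derived triplet when the
#' ancestral (outside modal) state is recorded, otherwise as position-state.
#'
#' @param f A `character_formula`.
#' @return A single string (empty for a `NULL`/empty formula).
#' @export
format_formula <- function(f) {
  if (is.null(f) || !length(f$terms)) return("")
  term_txt <- vapply(f$terms, function(t) {
    lit <- ifelse(is.na(t$ancestral),
                  paste0(t$position, t$state),
                  paste0(t$ancestral, t$position, t$state))
    paste(lit, collapse = " & ")
  }, character(1))
  paste(term_txt, collapse = " or ")
}

# literal satisfaction matrix: specimens x literals (TRUE = carries state)
literal_sat <- function(mat, lits) {
  sat <- matrix(FALSE, nrow(mat), nrow(lits))
  for (k in seq_len(nrow(lits))) sat[, k] <- mat[, lits$col[k]] == lits$state[k]
  sat
}

# data availability at literal positions: specimens x literals
literal_data <- function(mat, lits) {
  d <- matrix(FALSE, nrow(mat), nrow(lits))
  for (k in seq_len(nrow(lits))) d[, k] <- is_data_symbol(mat[, lits$col[k]])
  d
}

# Evaluate a candidate formula given per-literal satisfaction/data matrices.
# terms: list of integer vectors (literal indices). Returns TRUE iff the
# formula separates members from outsiders.
separates <- function(terms, msat, mdat, osat, odat) {
  n_mem <- nrow(msat)
  mem_sat <- rep(FALSE, n_mem)
  mem_dat <- rep(FALSE, n_mem)
  for (t in terms) {
    td <- if (length(t) == 1L) mdat[, t] else rowSums(mdat[, t, drop = FALSE]) == length(t)
    ts <- if (length(t) == 1L) msat[, t] else rowSums(msat[, t, drop = FALSE]) == length(t)
    mem_dat <- mem_dat | td
    mem_sat <- mem_sat | (td & ts)
    od <- if (length(t) == 1L) odat[, t] else rowSums(odat[, t, drop = FALSE]) == length(t)
    os <- if (length(t) == 1L) osat[, t] else rowSums(osat[, t, drop = FALSE]) == length(t)
    if (any(od & os)) return(FALSE)
  }
  any(mem_sat) && all(mem_sat[mem_dat])
}

#' Find a minimal separating barcode formula
#'
#' Searches the bounded DNF space (at most `formula_max_terms` terms of at
#' most `formula_max_literals` literals each) for a formula separating the
#' clade from all other specimens on the COI barcode, preferring fewest
#' literals, then fewest terms, then lexicographically least positions.
#' Where the clade is invariant at a separating position this reduces to a
#' one-literal formula (a plain diagnostic character).
#'
#' @param aln An [annotated_alignment()]; restricted internally to its COI
#'   locus when one is present, otherwise used whole.
#' @param members Non-empty clade member ids.
#' @param params [diagnostic_params()] supplying the search bounds.
#' @return A `character_formula`, or `NULL` (with a warning) when no
#'   separating formula exists within the bounds.
#' @export
find_barcode_formula <- function(aln, members, params = diagnostic_params()) {
  if ("COI" %in% aln$locus_index$locus_id &&
      nrow(aln$locus_index) > 1L) {
    aln <- extract_locus(aln, "COI")
  }
  locus <- aln$locus_index$locus_id[1L]
  ids <- specimen_ids(aln)
  outside <- setdiff(ids, members)
  if (!length(members) || !all(members %in% ids)) stop("bad member set")
  if (!length(outside)) stop("member set must leave outside specimens")

  mm <- aln$matrix[members, , drop = FALSE]
  oo <- aln$matrix[outside, , drop = FALSE]

  # candidate literals: (column, state) carried by at least one member
  cm <- base_counts(mm)
  hit <- which(cm > 0, arr.ind = TRUE)
  lits <- data.frame(col = hit[, 1L], state = BASES[hit[, 2L]])
  lits <- lits[order(lits$col, lits$state), ]
  rownames(lits) <- NULL
  if (!nrow(lits)) {
    warning("no candidate literals for formula search")
    return(NULL)
  }

  msat <- literal_sat(mm, lits); mdat <- literal_data(mm, lits)
  osat <- literal_sat(oo, lits); odat <- literal_data(oo, lits)

  max_t <- min(params$formula_max_terms, 2L)
  max_l <- min(params$formula_max_literals, 2L)
  nl <- nrow(lits)

  wrap <- function(terms) {
    new_formula(lapply(terms, function(t) {
      tl <- lits[t, , drop = FALSE]
      data.frame(locus_id = locus, position = tl$col,
                 ancestral = outside_modal(oo, tl$col, tl$state),
                 state = tl$state, stringsAsFactors = FALSE)
    }))
  }
  no_formula <- function() {
    warning("no separating formula within bounds (",
            max_t, " terms x ", max_l, " literals)")
    NULL
  }

  # 1 literal: vectorised screen over all literals (satisfaction implies
  # data, so a member is uncovered iff it has data but does not match)
  uncov1 <- colSums(mdat & !msat) > 0
  any1 <- colSums(msat) > 0
  clean1 <- colSums(osat) == 0
  sep1 <- which(clean1 & !uncov1 & any1)
  if (length(sep1)) return(wrap(list(sep1[1L])))

  if (max_l >= 2L && nl >= 2L) {
    # 2 literals, 1 term (conjunction): pairwise screens via crossprod
    S <- msat * 1; D <- mdat * 1; A <- (mdat & !msat) * 1; O <- osat * 1
    out_pair <- crossprod(O) > 0                       # an outsider matches both
    uncov_pair <- (crossprod(A, D) + crossprod(D, A)) > 0
    sat_pair <- crossprod(S) > 0
    same_col <- outer(lits$col, lits$col, "==")
    sep2 <- !out_pair & !uncov_pair & sat_pair & !same_col
    sep2[lower.tri(sep2, diag = TRUE)] <- FALSE
    hit <- which(sep2, arr.ind = TRUE)
    if (nrow(hit)) {
      hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
      return(wrap(list(c(hit[1L, 1L], hit[1L, 2L]))))
    }
  }

  if (max_t < 2L) return(no_formula())

  # Multi-term formulas: a minimal formula never contains a term that an
  # outsider satisfies (forbidden) or that no member satisfies (dropping it
  # cannot break separation), so candidate terms are the outsider-clean,
  # member-satisfied singletons and conjunctions. Whether a two-term formula
  # separates depends only on each term's satisfaction/data pattern over the
  # members, so terms are deduplicated by that pattern (keeping the
  # lexicographically first representative).
  cand1 <- which(clean1 & any1)
  if (length(cand1)) {
    key1 <- vapply(cand1, function(i) {
      paste(c(msat[, i], mdat[, i]), collapse = "")
    }, character(1))
    cand1 <- cand1[!duplicated(key1)]
  }
  # 2 literals, 2 terms (disjunction of two singletons)
  if (length(cand1) >= 2L) {
    for (a in seq_len(length(cand1) - 1L)) {
      for (b in (a + 1L):length(cand1)) {
        i <- cand1[a]; j <- cand1[b]
        covered <- !any((mdat[, i] | mdat[, j]) & !(msat[, i] | msat[, j]))
        if (covered) return(wrap(list(i, j)))
      }
    }
  }
  if (max_l < 2L) return(no_formula())

  cand2 <- {
    ok <- !out_pair & sat_pair & !same_col
    ok[lower.tri(ok, diag = TRUE)] <- FALSE
    h <- which(ok, arr.ind = TRUE)
    h <- h[order(h[, 1L], h[, 2L]), , drop = FALSE]
    if (nrow(h)) {
      key <- vapply(seq_len(nrow(h)), function(p) {
        i <- h[p, 1L]; j <- h[p, 2L]
        paste(c(msat[, i] & msat[, j], mdat[, i] & mdat[, j]), collapse = "")
      }, character(1))
      h <- h[!duplicated(key), , drop = FALSE]
    }
    h
  }
  check <- function(terms) {
    if (separates(terms, msat, mdat, osat, odat)) wrap(terms)
  }
  # 3 literals: conjunction + singleton
  if (nrow(cand2) && length(cand1)) {
    for (p in seq_len(nrow(cand2))) for (k in cand1) {
      t2 <- c(cand2[p, 1L], cand2[p, 2L])
      if (k %in% t2) next
      res <- check(list(t2, k))
      if (!is.null(res)) return(res)
    }
  }
  # 4 literals: two conjunctions
  if (nrow(cand2) >= 2L) {
    for (p in seq_len(nrow(cand2) - 1L)) for (q in (p + 1L):nrow(cand2)) {
      res <- check(list(c(cand2[p, 1L], cand2[p, 2L]),
                        c(cand2[q, 1L], cand2[q, 2L])))
      if (!is.null(res)) return(res)
    }
  }
  no_formula()
}

# unique outside state at a column (for rendering "anc pos state"); NA when
# outsiders are missing or polymorphic there, or carry the literal state.
outside_modal <- function(oo, cols, states) {
  vapply(seq_along(cols), function(k) {
    v <- oo[, cols[k]]
    v <- v[is_data_symbol(v)]
    u <- unique(v)
    if (length(u) == 1L && u != states[k]) u else NA_character_
  }, character(1))
}

#' Does a formula separate a clade on an alignment?
#'
#' Re-evaluates a `character_formula` on data (the soundness check used when
#' emitting diagnoses).
#'
#' @param aln An [annotated_alignment()].
#' @param members Clade member ids.
#' @param f A `character_formula` whose literals reference `aln`'s loci.
#' @return Logical scalar.
#' @export
formula_holds <- function(aln, members, f) {
  if (is.null(f) || !length(f$terms)) return(FALSE)
  ids <- specimen_ids(aln)
  outside <- setdiff(ids, members)
  cols <- lapply(f$terms, function(t)
    map_position(aln$locus_index, t$locus_id, t$position) + 1L)
  lits <- data.frame(col = unlist(cols),
                     state = unlist(lapply(f$terms, `[[`, "state")))
  idx <- split(seq_len(nrow(lits)),
               rep(seq_along(f$terms), vapply(f$terms, nrow, integer(1))))
  mm <- aln$matrix[members, , drop = FALSE]
  oo <- aln$matrix[outside, , drop = FALSE]
  separates(idx, literal_sat(mm, lits), literal_data(mm, lits),
            literal_sat(oo, lits), literal_data(oo, lits))
}
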