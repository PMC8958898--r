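# Independent brute-force oracles, written as literal restatements of the
# classification, formula-separation and MRCA rules. Deliberately plain
# (loops, tables) and sharing no code with the package internals.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_classify <- function(mat, members, col, frac = 0.05,
                            allow_ambiguity = FALSE) {
  m <- mat[members, col]
  o <- mat[setdiff(rownames(mat), members), col]
  m <- m[m %in% ORACLE_BASES]
  o <- o[o %in% ORACLE_BASES]
  if (length(m) == 0 || length(o) == 0) return(list(kind = "none"))
  tab <- table(factor(o, levels = ORACLE_BASES))
  modal <- names(tab)[which.max(tab)]   # alphabetical on ties
  deviators <- length(o) - max(tab)
  modal_ok <- deviators <= frac * length(o)
  states <- sort(unique(m))
  if (length(states) == 1) {
    s <- states
    if (any(o == s)) return(list(kind = "none"))
    if (modal_ok) return(list(kind = "direct", ancestral = modal, derived = s))
    return(list(kind = "state_only", ancestral = NA_character_, derived = s))
  }
  if (length(states) == 2 && allow_ambiguity && modal_ok &&
      !any(o %in% states)) {
    code <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
    return(list(kind = "ambiguous", ancestral = modal,
                derived = unname(code[paste(states, collapse = "")])))
  }
  list(kind = "none")
}

# Brute-force clade diagnosis: classify every column, order by (members
# missing, locus, position), truncate. Returns notation strings.
oracle_diagnose <- function(aln, members, frac = 0.05, k = 1000L,
                            allow_ambiguity = FALSE) {
  mat <- aln$matrix
  found <- character()
  nmiss <- integer()
  for (col in seq_len(ncol(mat))) {
    cl <- oracle_classify(mat, members, col, frac, allow_ambiguity)
    if (cl$kind == "none") next
    lp <- unmap_position(aln$locus_index, col - 1L)
    txt <- if (cl$kind == "state_only") {
      paste0(lp$locus_id, ":", lp$local_pos, cl$derived)
    } else {
      paste0(lp$locus_id, ":", cl$ancestral, lp$local_pos, cl$derived)
    }
    found <- c(found, txt)
    v <- mat[members, col]
    nmiss <- c(nmiss, sum(!v %in% ORACLE_BASES))
  }
  if (!length(found)) return(character())
  loc <- sub(":.*$", "", found)
  pos <- as.integer(gsub("[^0-9]", "", sub("^[^:]*:", "", found)))
  head(found[order(nmiss, loc, pos)], k)
}

# Formula-space oracle: minimum literal count of any separating DNF within
# (max_terms, max_literals), or Inf. Plain enumeration with loops.
oracle_min_formula_literals <- function(mat, members, max_terms = 2L,
                                        max_literals = 2L) {
  outside <- setdiff(rownames(mat), members)
  ncols <- ncol(mat)
  lits <- list()
  for (p in seq_len(ncols)) for (s in ORACLE_BASES) {
    if (any(mat[members, p] == s)) lits[[length(lits) + 1L]] <- list(p = p, s = s)
  }
  sat_term <- function(row, term) {
    for (l in term) {
      if (!row[l$p] %in% ORACLE_BASES || row[l$p] != l$s) return(FALSE)
    }
    TRUE
  }
  has_data_term <- function(row, term) {
    all(vapply(term, function(l) row[l$p] %in% ORACLE_BASES, logical(1)))
  }
  separates <- function(terms) {
    for (id in outside) {
      for (t in terms) if (sat_term(mat[id, ], t)) return(FALSE)
    }
    any_sat <- FALSE
    for (id in members) {
      row <- mat[id, ]
      relevant <- any(vapply(terms, has_data_term, logical(1), row = row))
      sat <- any(vapply(terms, sat_term, logical(1), row = row))
      if (sat) any_sat <- TRUE
      if (relevant && !sat) return(FALSE)
    }
    any_sat
  }
  nl <- length(lits)
  terms1 <- lapply(lits, list)
  terms2 <- list()
  if (max_literals >= 2L && nl >= 2L) {
    for (i in seq_len(nl - 1L)) for (j in (i + 1L):nl) {
      if (lits[[i]]$p != lits[[j]]$p) {
        terms2[[length(terms2) + 1L]] <- list(lits[[i]], lits[[j]])
      }
    }
  }
  # 1 literal
  for (t in terms1) if (separates(list(t))) return(1L)
  # 2 literals: one conjunction, then two singleton terms
  if (max_literals >= 2L) {
    for (t in terms2) if (separates(list(t))) return(2L)
  }
  if (max_terms >= 2L && nl >= 2L) {
    for (i in seq_len(nl - 1L)) for (j in (i + 1L):nl) {
      if (separates(list(terms1[[i]], terms1[[j]]))) return(2L)
    }
  }
  # 3 literals: conjunction + singleton
  if (max_terms >= 2L && max_literals >= 2L) {
    for (t2 in terms2) for (t1 in terms1) {
      if (separates(list(t2, t1))) return(3L)
    }
    # 4 literals: two conjunctions
    n2 <- length(terms2)
    if (n2 >= 2L) {
      for (i in seq_len(n2 - 1L)) for (j in (i + 1L):n2) {
        if (separates(list(terms2[[i]], terms2[[j]]))) return(4L)
      }
    }
  }
  Inf
}

# Naive MRCA tip set: recursively collect each node's tips, take the node
# covering all query tips with the smallest tip set.
oracle_mrca_tipset <- function(tree, tips) {
  ntip <- length(tree$tip.label)
  tipsets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- tree$tip.label[i]
  collect <- function(node) {
    if (node <= ntip) return(tipsets[[node]])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    out <- unlist(lapply(kids, collect))
    tipsets[[node]] <<- out
    out
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  collect(root)
  best <- NULL
  for (i in seq_along(tipsets)) {
    ts <- tipsets[[i]]
    if (!is.null(ts) && all(tips %in% ts)) {
      if (is.null(best) || length(ts) < length(best)) best <- ts
    }
  }
  sort(best)
}
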