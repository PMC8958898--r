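#' Assemble a diagnosis block
#'
#' Bundles the characters diagnosing a taxon: ranked nuclear characters, COI
#' barcode characters and/or a barcode formula, and optional notes. Emission
#' verifies every character against the source data; a block is never built
#' from stale characters.
#'
#' @param taxon Taxon name.
#' @param nuclear A [diag_characters()] frame (ranked).
#' @param coi A [diag_characters()] frame of barcode characters (may be empty).
#' @param formula Optional `character_formula` appended to the COI clause.
#' @param notes Optional free-text notes.
#' @param aln,members,sister When supplied, all characters are re-verified
#'   against the alignment and a violated character is an error; `sister`
#'   (and the implied parent set) contextualise small-clade characters.
#' @return A `diagnosis_block` list.
#' @export
diagnosis_block <- function(taxon, nuclear = empty_characters(),
                            coi = empty_characters(), formula = NULL,
                            notes = NULL, aln = NULL, members = NULL,
                            sister = NULL) {
  if (!is.null(aln) && !is.null(members)) {
    chk <- verify_characters(aln, members, rbind_characters(nuclear, coi),
                             sister = sister,
                             parent = if (!is.null(sister))
                               union(members, sister))
    if (any(!chk$holds)) {
      stop("diagnosis for ", taxon, " contains violated character(s): ",
           paste(format_character(chk[!chk$holds, ]), collapse = ", "))
    }
    if (!is.null(formula) && !formula_holds(aln, members, formula)) {
      stop("diagnosis for ", taxon, " contains a non-separating formula")
    }
  }
  structure(list(taxon = taxon, nuclear = nuclear, coi = coi,
                 formula = formula, notes = notes),
            class = "diagnosis_block")
}

#' Render a diagnosis block as text
#'
#' Mirrors the punctuation of printed taxon diagnoses:
#' `"nuclear genome: <c1>, <c2>, ...; COI barcode region: <b1>, ..."` with
#' characters in ranked order; retained characters keep their `"(not X)"`
#' annotation, and a disjunctive formula is rendered with `" or "` / `" & "`.
#' The COI clause is omitted when there are no barcode characters. Every
#' emitted character re-parses with [parse_character()].
#'
#' @param block A [diagnosis_block()].
#' @return A single formatted line.
#' @export
render_diagnosis <- function(block) {
  parts <- character()
  if (nrow(block$nuclear)) {
    parts <- c(parts, paste0("nuclear genome: ",
                             paste(format_character(block$nuclear),
                                   collapse = ", ")))
  }
  coi_items <- format_character(block$coi)
  ftxt <- format_formula(block$formula)
  if (nzchar(ftxt)) coi_items <- c(coi_items, ftxt)
  if (length(coi_items)) {
    parts <- c(parts, paste0("COI barcode region: ",
                             paste(coi_items, collapse = ", ")))
  }
  paste0(block$taxon, ": ", paste(parts, collapse = "; "))
}

#' Clade-pair divergence table
#'
#' One row per clade pair with min/mean/max percent COI divergence and the
#' number of defined cross pairs, sorted by descending mean — the table used
#' to compare a candidate taxon's divergence with genus-level and
#' subgenus-level bands.
#'
#' @param D A `distance_matrix` from [pairwise_matrix()].
#' @param clades Named list of label sets (at least two).
#' @return A data frame with columns `clade_a`, `clade_b`, `min_pct`,
#'   `mean_pct`, `max_pct`, `n_pairs`; a pair with no defined distances is
#'   flagged with `NA`s and `n_pairs = 0`.
#' @export
rank_comparison_table <- function(D, clades) {
  if (length(clades) < 2L) stop("need at least two clades")
  nm <- names(clades)
  rows <- list()
  for (i in seq_along(nm)[-length(nm)]) for (j in (i + 1L):length(nm)) {
    x <- D$d[clades[[i]], clades[[j]], drop = FALSE]
    x <- x[!is.na(x)]
    rows[[length(rows) + 1L]] <- data.frame(
      clade_a = nm[i], clade_b = nm[j],
      min_pct = if (length(x)) 100 * min(x) else NA_real_,
      mean_pct = if (length(x)) 100 * mean(x) else NA_real_,
      max_pct = if (length(x)) 100 * max(x) else NA_real_,
      n_pairs = length(x)
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_pct, out$clade_a, out$clade_b, na.last = TRUE), ]
  rownames(out) <- NULL
  out
}

#' Run the full diagnosis pipeline
#'
#' Simulates (or loads) a dataset, diagnoses every clade — choosing the
#' sister-complement mode for clades below `min_clade_size_direct` — finds
#' barcode characters and formulas, computes barcode distances, builds an NJ
#' tree, tests monophyly, and writes diagnoses, tables and a manifest. Fully
#' reproducible: the same config and seed give identical artifacts.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{seed}{integer, required.}
#'     \item{simulation}{optional list of [default_sim_config()] overrides
#'       (`background_rate`, `missing_max`); when absent, defaults are used.}
#'     \item{inputs}{alternatively, paths: `fasta`, `locus_table`, `tree`,
#'       `clades`, optional `coverage`.}
#'     \item{clades}{for simulated runs, optional character vector naming
#'       which clades to diagnose (default: all diagnosable).}
#'     \item{params}{optional list of [diagnostic_params()] overrides.}
#'     \item{barcode_start}{1-based barcode start in COI (default 1).}
#'     \item{outgroup}{tips used to root the NJ tree (default: none).}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the diagnosis blocks, divergence table,
#'   monophyly results, distance matrix, tree and manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config validation error: seed is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # stage warnings are collected into warnings.log rather than propagated
  warn_log <- character()
  collect <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warn_log <<- c(warn_log, paste0(stage, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  params <- do.call(diagnostic_params,
                    c(config$params %||% list()))

  if (!is.null(config$inputs)) {
    ins <- config$inputs
    aln <- read_alignment(ins$fasta, ins$locus_table)
    tree <- read_tree(ins$tree, aln)
    clades <- read_clades(ins$clades, aln)
    cov <- if (!is.null(ins$coverage)) read_coverage(ins$coverage, aln)
    truth <- NULL
  } else {
    sim_args <- config$simulation %||% list()
    cfg <- do.call(default_sim_config, c(list(seed = config$seed), sim_args))
    sim <- simulate_dataset(cfg)
    aln <- sim$alignment; tree <- sim$tree; cov <- sim$coverage
    clades <- cfg$clades
    truth <- sim$truth
    write_alignment(aln, file.path(out_dir, "alignment.fasta"),
                    file.path(out_dir, "loci.tsv"))
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_truth(truth, file.path(out_dir, "truth.json"))
  }
  if (is.null(clades) || !length(clades)) {
    stop("config validation error: no clades to diagnose")
  }
  if (!is.null(config$clades)) clades <- clades[config$clades]

  nuc <- extract_partition(aln, "nuclear")
  barcode <- extract_barcode(aln, config$barcode_start %||% 1L)
  nuc_cov <- if (!is.null(cov)) {
    cols <- unlist(lapply(nuc$locus_index$locus_id, locus_columns,
                          idx = aln$locus_index))
    cov[, cols, drop = FALSE]
  }

  ids <- specimen_ids(aln)
  diagnosable <- Filter(function(m) length(m) < length(ids), clades)
  blocks <- list()
  for (nm in names(diagnosable)) {
    members <- diagnosable[[nm]]
    small <- length(members) < params$min_clade_size_direct
    sister <- NULL
    if (small) {
      sister <- sister_tips(tree, members)
      nuclear <- collect(paste0("diagnose[", nm, "]"),
                         diagnose_small_clade(nuc, tree, members,
                                              cov = nuc_cov, params = params))
      coi <- empty_characters()
      f <- NULL
    } else {
      nuclear <- collect(paste0("diagnose[", nm, "]"),
                         diagnose_clade(nuc, members, cov = nuc_cov,
                                        params = params))
      coi <- rank_characters(candidate_characters(barcode, members, params,
                                                  allow_ambiguity = TRUE))
      coi <- utils::head(coi, params$k_report)
      f <- if (!nrow(coi)) {
        collect(paste0("barcode[", nm, "]"),
                find_barcode_formula(barcode, members, params))
      }
    }
    # verify at emission time: nuclear against the full alignment, barcode
    # characters against the barcode coordinate system they are written in
    chk <- verify_characters(aln, members, nuclear, sister = sister,
                             parent = if (!is.null(sister))
                               union(members, sister))
    chk_coi <- verify_characters(barcode, members, coi)
    bad <- c(format_character(chk[!chk$holds, ]),
             format_character(chk_coi[!chk_coi$holds, ]))
    if (length(bad)) {
      stop("diagnose stage: violated character(s) for ", nm, ": ",
           paste(bad, collapse = ", "))
    }
    if (!is.null(f) && !formula_holds(barcode, members, f)) {
      stop("diagnose stage: non-separating formula for ", nm)
    }
    blocks[[nm]] <- diagnosis_block(nm, nuclear = nuclear, coi = coi,
                                    formula = f)
  }

  D <- pairwise_matrix(barcode)
  div_table <- rank_comparison_table(D, diagnosable)
  mono <- do.call(rbind, lapply(names(diagnosable), function(nm) {
    m <- check_monophyly(tree, diagnosable[[nm]])
    data.frame(clade = nm, is_monophyletic = m$is_monophyletic,
               mrca_size = m$mrca_size,
               intruders = paste(m$intruders, collapse = ","))
  }))
  njt <- if (length(ids) >= 3L) collect("nj", nj_tree(D))
  if (!is.null(njt) && !is.null(config$outgroup)) {
    njt <- root_with_outgroup(njt, config$outgroup)
  }

  writeLines(vapply(blocks, render_diagnosis, character(1)),
             file.path(out_dir, "diagnoses.txt"))
  writeLines(warn_log, file.path(out_dir, "warnings.log"))
  utils::write.table(div_table, file.path(out_dir, "divergence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(mono, file.path(out_dir, "monophyly.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_distance_matrix(D, file.path(out_dir, "distances.tsv"))
  if (!is.null(njt)) ape::write.tree(njt, file.path(out_dir, "nj_tree.nwk"))

  manifest <- list(
    package = "taxodiag",
    version = as.character(utils::packageVersion("taxodiag")),
    seed = config$seed,
    params = unclass(params),
    n_specimens = length(ids),
    n_columns = ncol(aln$matrix),
    clades = lapply(diagnosable, identity),
    simulated = is.null(config$inputs),
    n_warnings = length(warn_log)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(blocks = blocks, divergence = div_table, monophyly = mono,
                 distances = D, nj_tree = njt, truth = truth,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
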