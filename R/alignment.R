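#' Annotated multi-locus alignment
#'
#' A specimen-by-column nucleotide matrix partitioned into named loci.
#' Symbols are upper-case characters over the IUPAC alphabet plus `N` and
#' `-`; `?` in input is normalised to `N`.
#'
#' @param matrix Character matrix, rows named by specimen ids.
#' @param locus_index A [locus_index()] whose total length equals `ncol(matrix)`.
#' @return An `annotated_alignment` object (list with elements `matrix` and
#'   `locus_index`).
#' @export
annotated_alignment <- function(matrix, locus_index) {
  if (is.null(rownames(matrix))) stop("matrix rows must be named by specimen id")
  if (anyDuplicated(rownames(matrix))) stop("duplicate specimen ids")
  matrix[] <- toupper(matrix)
  matrix[matrix == "?"] <- "N"
  bad <- !(matrix %in% ALPHABET)
  if (any(bad)) {
    stop("illegal alignment symbol(s): ",
         paste(unique(matrix[bad]), collapse = " "))
  }
  if (ncol(matrix) != n_columns(locus_index)) {
    stop("sum of locus lengths (", n_columns(locus_index),
         ") does not match alignment width (", ncol(matrix), ")")
  }
  structure(list(matrix = matrix, locus_index = locus_index),
            class = "annotated_alignment")
}

#' @export
print.annotated_alignment <- function(x, ...) {
  cat("annotated_alignment:", nrow(x$matrix), "specimens x",
      ncol(x$matrix), "columns;", nrow(x$locus_index), "loci\n")
  invisible(x)
}

specimen_ids <- function(aln) rownames(aln$matrix)

#' Read an aligned FASTA plus locus table
#'
#' @param fasta_path Aligned FASTA, one record per specimen.
#' @param locus_table_path TSV with columns `locus_id` and `length` in
#'   concatenation order (an optional third column `partition` gives
#'   `nuclear`/`mito`; by default only the reserved locus `COI` is mito).
#' @return An [annotated_alignment()].
#' @export
read_alignment <- function(fasta_path, locus_table_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) > 1L) {
    stop("alignment error: sequences have unequal lengths (",
         paste(unique(w), collapse = ", "), ")")
  }
  tab <- utils::read.delim(locus_table_path, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("locus_id", "length") %in% names(tab))) {
    stop("locus table must have columns locus_id and length")
  }
  idx <- locus_index(tab$locus_id, tab$length,
                     partition = if ("partition" %in% names(tab)) tab$partition)
  mat <- do.call(rbind, strsplit(as.character(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  annotated_alignment(mat, idx)
}

#' Write an alignment as FASTA plus locus table
#'
#' Inverse of [read_alignment()]: reading back what was written reproduces the
#' alignment content exactly (symbols, specimen order, locus table).
#'
#' @param aln An [annotated_alignment()].
#' @param fasta_path,locus_table_path Output paths.
#' @export
write_alignment <- function(aln, fasta_path, locus_table_path) {
  seqs <- Biostrings::BStringSet(apply(aln$matrix, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(seqs, fasta_path)
  utils::write.table(
    aln$locus_index[, c("locus_id", "length", "partition")],
    locus_table_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(aln)
}

#' Restrict an alignment to one locus or partition
#'
#' @param aln An [annotated_alignment()].
#' @param locus_id A locus to extract; its positions are renumbered 1..length.
#' @return An [annotated_alignment()] over the selected columns.
#' @export
extract_locus <- function(aln, locus_id) {
  cols <- locus_columns(aln$locus_index, locus_id)
  i <- match(locus_id, aln$locus_index$locus_id)
  idx <- locus_index(locus_id, length(cols),
                     partition = aln$locus_index$partition[i])
  annotated_alignment(aln$matrix[, cols, drop = FALSE], idx)
}

#' @rdname extract_locus
#' @param partition `"nuclear"` or `"mito"`.
#' @export
extract_partition <- function(aln, partition) {
  keep <- aln$locus_index$partition == partition
  if (!any(keep)) stop("no loci in partition ", partition)
  sub <- aln$locus_index[keep, ]
  cols <- unlist(lapply(sub$locus_id, locus_columns, idx = aln$locus_index))
  idx <- locus_index(sub$locus_id, sub$length, partition = sub$partition)
  annotated_alignment(aln$matrix[, cols, drop = FALSE], idx)
}

#' Read a per-specimen, per-position read-depth table
#'
#' @param tsv_path TSV with columns `specimen_id`, `locus_id`, `local_pos`,
#'   `depth`. Cells absent from the table get depth 0.
#' @param aln The paired [annotated_alignment()]; dimensions and the
#'   depth-0-iff-missing invariant are validated against it.
#' @return An integer matrix of depths with the alignment's dimnames.
#' @export
read_coverage <- function(tsv_path, aln) {
  tab <- utils::read.delim(tsv_path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("specimen_id", "locus_id", "local_pos", "depth")
  if (!all(need %in% names(tab))) {
    stop("coverage table must have columns ", paste(need, collapse = ", "))
  }
  if (any(tab$depth < 0)) stop("value error: negative read depth")
  unknown <- setdiff(tab$specimen_id, specimen_ids(aln))
  if (length(unknown)) stop("coverage names unknown specimen: ",
                            paste(unknown, collapse = ", "))
  depth <- matrix(0L, nrow(aln$matrix), ncol(aln$matrix),
                  dimnames = dimnames(aln$matrix))
  col <- map_position(aln$locus_index, tab$locus_id, tab$local_pos) + 1L
  depth[cbind(match(tab$specimen_id, specimen_ids(aln)), col)] <-
    as.integer(tab$depth)
  validate_coverage(depth, aln)
  depth
}

validate_coverage <- function(depth, aln) {
  if (!identical(dim(depth), dim(aln$matrix))) {
    stop("coverage dimensions do not match alignment")
  }
  miss <- aln$matrix %in% MISSING_SYMBOLS
  if (any(depth[miss] != 0L)) stop("positive depth at missing alignment cell")
  if (any(depth[!miss] == 0L)) stop("zero depth at non-missing alignment cell")
  invisible(depth)
}

#' Write a coverage matrix as a long TSV
#'
#' Only cells with positive depth are written (depth 0 is implied elsewhere).
#' @param depth Integer depth matrix paired with `aln`.
#' @param aln The paired [annotated_alignment()].
#' @param tsv_path Output path.
#' @export
write_coverage <- function(depth, aln, tsv_path) {
  pos <- which(depth > 0L, arr.ind = TRUE)
  lp <- unmap_position(aln$locus_index, pos[, 2L] - 1L)
  tab <- data.frame(
    specimen_id = specimen_ids(aln)[pos[, 1L]],
    locus_id = lp$locus_id,
    local_pos = lp$local_pos,
    depth = depth[pos]
  )
  tab <- tab[order(tab$specimen_id, tab$locus_id, tab$local_pos), ]
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read clade definitions
#'
#' @param tsv_path TSV with columns `clade_name` and `specimen_id`, one row
#'   per member.
#' @param aln Optional [annotated_alignment()]; when given, membership is
#'   validated against its specimens.
#' @return Named list of character vectors (clade name -> member ids).
#' @export
read_clades <- function(tsv_path, aln = NULL) {
  tab <- utils::read.delim(tsv_path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("clade_name", "specimen_id") %in% names(tab))) {
    stop("clade table must have columns clade_name and specimen_id")
  }
  if (!is.null(aln)) {
    unknown <- setdiff(tab$specimen_id, specimen_ids(aln))
    if (length(unknown)) {
      stop("membership error: unknown specimen ",
           paste(unknown, collapse = ", "))
    }
  }
  lapply(split(tab$specimen_id, tab$clade_name), unique)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that rejects duplicate tip labels and
#' optionally validates tips against an alignment's specimens.
#'
#' @param newick_path Path to a Newick file.
#' @param aln Optional [annotated_alignment()] whose specimen set must contain
#'   all tip labels.
#' @return An [ape::phylo] tree.
#' @export
read_tree <- function(newick_path, aln = NULL) {
  tree <- ape::read.tree(newick_path)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels in tree")
  if (!is.null(aln)) {
    unknown <- setdiff(tree$tip.label, specimen_ids(aln))
    if (length(unknown)) {
      stop("tree tip not in alignment: ", paste(unknown, collapse = ", "))
    }
  }
  tree
}
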