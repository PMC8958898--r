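#' Locus index for a concatenated alignment
#'
#' Describes how a concatenated multi-locus alignment is partitioned into
#' named loci. Locus identifiers follow the `cne<scaffold>.<gene>.<exon>`
#' convention of the reference exon set (e.g. `cne1547.14.1` is exon 1 of
#' gene 14 from scaffold 1547); the reserved id `"COI"` denotes the
#' mitochondrial barcode locus. Identifiers are treated as opaque keys.
#'
#' @param locus_id Character vector of unique locus identifiers, in
#'   concatenation order.
#' @param length Integer vector of locus lengths (positions), all >= 1.
#' @param partition Optional character vector, `"nuclear"` or `"mito"` per
#'   locus. Defaults to `"mito"` for the `"COI"` locus and `"nuclear"`
#'   otherwise.
#' @return A `locus_index` data frame with columns `locus_id`, `length`,
#'   `offset` (0-based start column in the concatenated alignment) and
#'   `partition`. Offsets are contiguous: `offset[i+1] == offset[i] + length[i]`.
#' @export
locus_index <- function(locus_id, length, partition = NULL) {
  locus_id <- as.character(locus_id)
  length <- as.integer(length)
  if (anyDuplicated(locus_id)) stop("duplicate locus ids")
  if (any(is.na(length)) || any(length < 1L)) stop("locus lengths must be >= 1")
  if (is.null(partition)) {
    partition <- ifelse(locus_id == "COI", "mito", "nuclear")
  }
  partition <- as.character(partition)
  if (!all(partition %in% c("nuclear", "mito"))) {
    stop("partition must be 'nuclear' or 'mito'")
  }
  idx <- data.frame(
    locus_id = locus_id,
    length = length,
    offset = cumsum(c(0L, length[-base::length(length)])),
    partition = partition,
    stringsAsFactors = FALSE
  )
  class(idx) <- c("locus_index", "data.frame")
  idx
}

n_columns <- function(idx) sum(idx$length)

#' Map a within-locus position to a global alignment column
#'
#' Positions are 1-based within their locus (as in character notation such as
#' `cne1547.14.1:T789C`, which refers to position 789 of that exon); global
#' columns are 0-based.
#'
#' @param idx A [locus_index()].
#' @param locus_id Locus identifier.
#' @param local_pos 1-based position within the locus.
#' @return 0-based global column index.
#' @seealso [unmap_position()] for the inverse.
#' @export
map_position <- function(idx, locus_id, local_pos) {
  i <- match(locus_id, idx$locus_id)
  if (anyNA(i)) {
    stop("unknown locus: ", paste(locus_id[is.na(i)], collapse = ", "))
  }
  local_pos <- as.integer(local_pos)
  bad <- local_pos < 1L | local_pos > idx$length[i]
  if (any(bad)) {
    stop("position out of range for locus ", paste(locus_id[bad], collapse = ", "))
  }
  idx$offset[i] + local_pos - 1L
}

#' Map a global alignment column back to (locus, position)
#'
#' @param idx A [locus_index()].
#' @param global 0-based global column index (vectorised).
#' @return A data frame with columns `locus_id` and `local_pos` (1-based).
#' @export
unmap_position <- function(idx, global) {
  global <- as.integer(global)
  if (any(global < 0L) || any(global >= n_columns(idx))) {
    stop("global column out of range")
  }
  i <- findInterval(global, idx$offset)
  data.frame(
    locus_id = idx$locus_id[i],
    local_pos = global - idx$offset[i] + 1L,
    stringsAsFactors = FALSE
  )
}

#' Global columns spanned by a locus
#' @keywords internal
locus_columns <- function(idx, locus_id) {
  i <- match(locus_id, idx$locus_id)
  if (is.na(i)) stop("unknown locus: ", locus_id)
  seq.int(idx$offset[i] + 1L, idx$offset[i] + idx$length[i]) # 1-based for R
}
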