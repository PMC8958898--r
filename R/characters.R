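#' Diagnostic character records
#'
#' A set of diagnostic characters is kept as a data frame with one row per
#' character and columns:
#' \describe{
#'   \item{locus_id}{locus identifier; `"COI"` for barcode characters.}
#'   \item{position}{1-based position within the locus.}
#'   \item{ancestral}{ancestral base, or `NA` when unclear (`state_only`).}
#'   \item{derived}{clade state: a base, or a two-fold IUPAC code when the
#'     clade is polymorphic; for `retained_not` this is the retained
#'     (ancestral) state.}
#'   \item{kind}{`"direct"`, `"state_only"` or `"retained_not"`.}
#'   \item{excluded_state}{for `retained_not` only: the sister clade's state
#'     that the diagnosed clade does not carry.}
#'   \item{scope}{`"focal"`, `"parent"` or `"sister_negated"`.}
#'   \item{n_missing}{clade members without data at the position.}
#'   \item{min_depth, mean_depth}{read-depth summaries over clade members
#'     with data (`NA` without coverage).}
#' }
#'
#' @param locus_id,position,ancestral,derived,kind,excluded_state,scope,n_missing,min_depth,mean_depth
#'   Per-character fields, recycled to a common length.
#' @return A `diag_characters` data frame.
#' @export
diag_characters <- function(locus_id = character(), position = integer(),
                            ancestral = NA_character_, derived = character(),
                            kind = "direct", excluded_state = NA_character_,
                            scope = "focal", n_missing = NA_integer_,
                            min_depth = NA_real_, mean_depth = NA_real_) {
  if (!length(locus_id)) {
    df <- data.frame(locus_id = character(), position = integer(),
                     ancestral = character(), derived = character(),
                     kind = character(), excluded_state = character(),
                     scope = character(), n_missing = integer(),
                     min_depth = numeric(), mean_depth = numeric(),
                     stringsAsFactors = FALSE)
    class(df) <- c("diag_characters", "data.frame")
    return(df)
  }
  df <- data.frame(
    locus_id = as.character(locus_id), position = as.integer(position),
    ancestral = as.character(ancestral), derived = as.character(derived),
    kind = as.character(kind), excluded_state = as.character(excluded_state),
    scope = as.character(scope), n_missing = as.integer(n_missing),
    min_depth = as.numeric(min_depth), mean_depth = as.numeric(mean_depth),
    stringsAsFactors = FALSE
  )
  validate_characters(df)
  class(df) <- c("diag_characters", "data.frame")
  df
}

validate_characters <- function(df) {
  if (!nrow(df)) return(invisible(df))
  stopifnot(df$kind %in% c("direct", "state_only", "retained_not"),
            df$scope %in% c("focal", "parent", "sister_negated"),
            df$position >= 1L)
  d <- df$kind == "direct"
  if (any(d & (is.na(df$ancestral) | df$ancestral == df$derived))) {
    stop("direct characters need ancestral != derived")
  }
  r <- df$kind == "retained_not"
  if (any(r & is.na(df$excluded_state))) {
    stop("retained_not characters need an excluded state")
  }
  invisible(df)
}

CHAR_RE <- list(
  retained_not = "^([ACGT])([0-9]+)([ACGT]) \\(not ([ACGT])\\)$",
  direct = "^([ACGT])([0-9]+)([ACGTRYSWKM])$",
  state_only = "^([0-9]+)([ACGT])$"
)

#' Parse diagnostic-character notation
#'
#' Accepts the compact notation used in taxon diagnoses:
#' `cne1547.14.1:T789C` (position 789 of that exon changed from ancestral T
#' to C), `cne1086.2.12:G82G (not A)` (position 82 retains ancestral G while
#' the sister clade changed it to A) and `cneX.1.1:145A` (position 145 is A,
#' ancestral state unclear). Characters without a locus prefix are COI
#' barcode characters; whitespace after the colon is tolerated. Parsing is
#' case-insensitive apart from locus ids.
#'
#' @param text Character vector of notations.
#' @return A [diag_characters()] data frame, one row per input.
#' @seealso [format_character()], its inverse.
#' @export
parse_character <- function(text) {
  text <- trimws(text)
  has_locus <- grepl(":", text, fixed = TRUE)
  locus <- ifelse(has_locus, sub(":.*$", "", text), "COI")
  body <- trimws(ifelse(has_locus, sub("^[^:]*:", "", text), text))
  one <- function(locus, body, orig) {
    m <- regmatches(body, regexec(CHAR_RE$retained_not, body))[[1]]
    if (length(m)) {
      if (m[2] != m[4]) stop("parse error (retained state mismatch): ", orig)
      return(diag_characters(locus, as.integer(m[3]), ancestral = m[2],
                             derived = m[2], kind = "retained_not",
                             excluded_state = m[5], scope = "sister_negated"))
    }
    m <- regmatches(body, regexec(CHAR_RE$direct, body))[[1]]
    if (length(m)) {
      if (m[2] == m[4]) stop("parse error (ancestral = derived): ", orig)
      return(diag_characters(locus, as.integer(m[3]), ancestral = m[2],
                             derived = m[4], kind = "direct"))
    }
    m <- regmatches(body, regexec(CHAR_RE$state_only, body))[[1]]
    if (length(m)) {
      return(diag_characters(locus, as.integer(m[2]), ancestral = NA,
                             derived = m[3], kind = "state_only"))
    }
    stop("parse error: malformed character '", orig, "'")
  }
  body <- sub(" \\(NOT ", " (not ", toupper(body))  # states upper, keyword low
  out <- mapply(one, locus, body, text, SIMPLIFY = FALSE)
  do.call(rbind_characters, out)
}

#' Format diagnostic characters in diagnosis notation
#'
#' Inverse of [parse_character()]: `parse_character(format_character(x))`
#' reproduces the locus, position, states and kind. COI characters are
#' written without a locus prefix.
#'
#' @param dc A [diag_characters()] data frame.
#' @return Character vector, one notation per row.
#' @export
format_character <- function(dc) {
  if (!nrow(dc)) return(character())
  body <- character(nrow(dc))
  d <- dc$kind == "direct"
  body[d] <- paste0(dc$ancestral[d], dc$position[d], dc$derived[d])
  s <- dc$kind == "state_only"
  body[s] <- paste0(dc$position[s], dc$derived[s])
  r <- dc$kind == "retained_not"
  body[r] <- paste0(dc$derived[r], dc$position[r], dc$derived[r],
                    " (not ", dc$excluded_state[r], ")")
  ifelse(dc$locus_id == "COI", body, paste0(dc$locus_id, ":", body))
}

# rbind for diag_characters that keeps the class and tolerates empties.
rbind_characters <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(parts)) return(diag_characters())
  out <- do.call(rbind, lapply(parts, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("diag_characters", "data.frame")
  out
}

empty_characters <- function() diag_characters()
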