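#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of unique sequence labels.
#' @param rows Character vector of equal-length aligned sequences (gap
#'   `'-'`; `'.'` is normalised to `'-'`).
#' @return Object of class `msa`.
#' @export
msa <- function(ids, rows) {
  stopifnot(length(ids) == length(rows), !anyDuplicated(ids))
  ids <- unname(ids)
  rows <- unname(gsub(".", "-", toupper(rows), fixed = TRUE))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) stop("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ok <- mat %in% c(names(average_residue_masses()), "-")
  if (!all(ok)) {
    stop("alignment contains characters outside the 20 amino-acid letters and '-'")
  }
  rownames(mat) <- ids
  structure(list(ids = ids, rows = rows, mat = mat, ncol = lens[1L]),
            class = "msa")
}

#' Read an aligned FASTA file
#'
#' Gap characters `'-'` and `'.'` are both accepted; `'.'` is normalised to
#' `'-'`.
#'
#' @param path Path to an aligned FASTA file.
#' @return An [msa()] object.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  msa(names(set), as.character(set))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

#' Map an alignment column to an unaligned sequence position
#'
#' Returns the count of non-gap characters in the row up to and including
#' the column (1-based), or `NA` if the row has a gap at that column.
#'
#' @param alignment An [msa()].
#' @param seq_id Row label.
#' @param column 1-based alignment column.
#' @return Integer unaligned position, or `NA_integer_` for a gap.
#' @export
map_position <- function(alignment, seq_id, column) {
  stopifnot(inherits(alignment, "msa"))
  if (!seq_id %in% alignment$ids) {
    stop(sprintf("unknown sequence id '%s'", seq_id))
  }
  if (column < 1L || column > alignment$ncol) stop("column out of range")
  row <- alignment$mat[seq_id, ]
  if (row[column] == "-") return(NA_integer_)
  sum(row[seq_len(column)] != "-")
}

#' Map an unaligned sequence position to its alignment column
#'
#' Inverse of [map_position()] on non-gap positions.
#'
#' @param alignment An [msa()].
#' @param seq_id Row label.
#' @param position 1-based position in the ungapped sequence.
#' @return 1-based alignment column.
#' @export
unmap_position <- function(alignment, seq_id, position) {
  stopifnot(inherits(alignment, "msa"))
  if (!seq_id %in% alignment$ids) {
    stop(sprintf("unknown sequence id '%s'", seq_id))
  }
  row <- alignment$mat[seq_id, ]
  nongap <- which(row != "-")
  if (position < 1L || position > length(nongap)) {
    stop(sprintf("position %d outside the ungapped sequence (length %d)",
                 position, length(nongap)))
  }
  nongap[position]
}

#' Default physicochemical similarity classes
#'
#' A common grouping of the 20 amino acids: aliphatic `{G,A,V,L,I}`,
#' aromatic `{F,Y,W}`, sulfur-containing `{C,M}`, hydroxyl `{S,T}`, basic
#' `{K,R,H}`, acidic/amide `{D,E,N,Q}`, and `{P}`. Explicitly configurable:
#' any disjoint cover of the 20 letters is accepted wherever a `classes`
#' argument appears.
#'
#' @return List of character vectors partitioning the 20 letters.
#' @export
default_similarity_classes <- function() {
  list(
    aliphatic = c("G", "A", "V", "L", "I"),
    aromatic = c("F", "Y", "W"),
    sulfur = c("C", "M"),
    hydroxyl = c("S", "T"),
    basic = c("K", "R", "H"),
    acidic_amide = c("D", "E", "N", "Q"),
    proline = "P"
  )
}

check_classes <- function(classes) {
  all20 <- names(average_residue_masses())
  flat <- unlist(classes)
  if (anyDuplicated(flat) || !setequal(flat, all20)) {
    stop("similarity classes must partition the 20 amino-acid letters exactly")
  }
  invisible(TRUE)
}

column_residues <- function(alignment, column) {
  if (column < 1L || column > alignment$ncol) stop("column out of range")
  chars <- alignment$mat[, column]
  chars[chars != "-"]
}

pairwise_match_pct <- function(groups) {
  n <- length(groups)
  if (n < 2L) return(NA_real_)
  counts <- table(groups)
  same <- sum(choose(counts, 2))
  100 * same / choose(n, 2)
}

#' Per-column percent identity
#'
#' Mean pairwise identity over the non-gap residues of the column:
#' 100 * (matching pairs) / (all pairs). Gaps are excluded pairwise.
#' `method = "modal"` instead reports the frequency of the most common
#' residue (a sensitivity-analysis alternative).
#'
#' @param alignment An [msa()].
#' @param column 1-based column index.
#' @param method `"pairwise"` (default) or `"modal"`.
#' @return Percent identity, or `NA` if fewer than 2 non-gap residues.
#' @export
column_identity <- function(alignment, column, method = c("pairwise", "modal")) {
  method <- match.arg(method)
  res <- column_residues(alignment, column)
  if (length(res) < 2L) return(NA_real_)
  if (method == "modal") {
    return(100 * max(table(res)) / length(res))
  }
  pairwise_match_pct(res)
}

#' Per-column percent similarity
#'
#' As [column_identity()], but residues match when they fall in the same
#' similarity class: 100 * (same-class pairs) / (all pairs).
#'
#' @param alignment An [msa()].
#' @param column 1-based column index.
#' @param classes Similarity classes (see [default_similarity_classes()]).
#' @return Percent similarity, or `NA` if fewer than 2 non-gap residues.
#' @export
column_similarity <- function(alignment, column,
                              classes = default_similarity_classes()) {
  check_classes(classes)
  res <- column_residues(alignment, column)
  if (length(res) < 2L) return(NA_real_)
  class_of <- rep(seq_along(classes), lengths(classes))
  names(class_of) <- unlist(classes)
  pairwise_match_pct(class_of[res])
}

#' Per-column statistics for an alignment
#'
#' @param alignment An [msa()].
#' @param columns Columns to score (default all).
#' @param classes Similarity classes.
#' @return Data frame with `column`, `identity_pct`, `similarity_pct`,
#'   `modal_residue` and `gap_fraction`.
#' @export
column_stats <- function(alignment, columns = seq_len(alignment$ncol),
                         classes = default_similarity_classes()) {
  rows <- lapply(columns, function(j) {
    chars <- alignment$mat[, j]
    res <- chars[chars != "-"]
    modal <- if (length(res)) names(which.max(table(res))) else "-"
    data.frame(
      column = j,
      identity_pct = column_identity(alignment, j),
      similarity_pct = column_similarity(alignment, j, classes),
      modal_residue = modal,
      gap_fraction = mean(chars == "-"),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Mean identity/similarity over a set of interface columns
#'
#' Unweighted mean of the defined per-column statistics over the given
#' columns; columns with fewer than two non-gap residues are reported as
#' skipped and excluded from the averages.
#'
#' @param alignment An [msa()].
#' @param interface_columns 1-based column indices (nonempty).
#' @param classes Similarity classes.
#' @return List with `mean_identity_pct`, `mean_similarity_pct`,
#'   `n_columns`, `skipped_columns`.
#' @export
interface_conservation_summary <- function(alignment, interface_columns,
                                           classes = default_similarity_classes()) {
  stopifnot(length(interface_columns) >= 1L)
  stats <- column_stats(alignment, interface_columns, classes)
  defined <- !is.na(stats$identity_pct)
  if (!any(defined)) {
    stop("all requested columns are undefined (fewer than 2 non-gap residues)")
  }
  list(
    mean_identity_pct = mean(stats$identity_pct[defined]),
    mean_similarity_pct = mean(stats$similarity_pct[defined]),
    n_columns = sum(defined),
    skipped_columns = stats$column[!defined]
  )
}

#' Write per-column statistics to CSV
#'
#' @param stats Data frame from [column_stats()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_column_stats <- function(stats, path) {
  utils::write.csv(stats, path, row.names = FALSE)
  invisible(path)
}
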