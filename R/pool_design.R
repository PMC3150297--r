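#' Build a bi-dimensional overlapping pool design
#'
#' In a bi-dimensional TILLING screen a plate of \code{n_rows * n_cols} wells,
#' each holding \code{i_well} mutagenized individuals, is pooled twice: every
#' row of wells forms one sequencing library and every column another, so each
#' individual's DNA occurs in exactly two libraries. The canonical screen uses
#' 8 row pools and 12 column pools over a 96-well plate with 8 individuals per
#' well (768 individuals, 20 libraries).
#'
#' @param n_rows Number of row pools (>= 1).
#' @param n_cols Number of column pools (>= 1).
#' @param i_well Individuals pooled per well (>= 1).
#' @return An object of class \code{pool_design}: a list with elements
#'   \code{n_rows}, \code{n_cols}, \code{i_well}, \code{n_w} (well count),
#'   \code{rows}, \code{cols} (library identifiers \code{"R1"..}, \code{"C1"..}),
#'   \code{libraries} (data frame with \code{library}, \code{type},
#'   \code{i_l}), and \code{wells} (data frame with \code{well}, \code{row},
#'   \code{col}, and integer indices \code{row_idx}, \code{col_idx} into
#'   \code{libraries}).
#' @examples
#' d <- build_design(8, 12, 8)
#' d$n_w                     # 96 wells
#' nrow(d$libraries)         # 20 libraries
#' @export
build_design <- function(n_rows, n_cols, i_well) {
  for (a in c(n_rows, n_cols, i_well)) {
    if (length(a) != 1L || !is.finite(a) || a < 1 || a != round(a))
      stop("invalid design: n_rows, n_cols and i_well must be positive integers")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  i_well <- as.integer(i_well)
  rows <- paste0("R", seq_len(n_rows))
  cols <- paste0("C", seq_len(n_cols))
  libraries <- data.frame(
    library = c(rows, cols),
    type    = rep(c("row", "col"), c(n_rows, n_cols)),
    i_l     = c(rep(n_cols * i_well, n_rows), rep(n_rows * i_well, n_cols)),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(col_idx = seq_len(n_cols), row_idx = seq_len(n_rows))
  wells <- data.frame(
    well    = sprintf("(%s,%s)", rows[grid$row_idx], cols[grid$col_idx]),
    row     = rows[grid$row_idx],
    col     = cols[grid$col_idx],
    row_idx = grid$row_idx,
    col_idx = as.integer(n_rows + grid$col_idx),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols, i_well = i_well,
         n_w = n_rows * n_cols, rows = rows, cols = cols,
         libraries = libraries, wells = wells),
    class = "pool_design"
  )
}

#' @export
print.pool_design <- function(x, ...) {
  cat(sprintf("pool_design: %d rows x %d cols, %d wells, %d individuals/well (%d total)\n",
              x$n_rows, x$n_cols, x$n_w, x$i_well, x$n_w * x$i_well))
  invisible(x)
}

#' Libraries containing a well
#'
#' @param design A \code{pool_design}.
#' @param w A well identifier as produced by \code{\link{build_design}},
#'   e.g. \code{"(R3,C7)"}.
#' @return Character vector of length two: the row library and the column
#'   library whose intersection is the well.
#' @export
libraries_for_well <- function(design, w) {
  stopifnot(inherits(design, "pool_design"))
  i <- match(w, design$wells$well)
  if (is.na(i)) stop("unknown well: ", w)
  c(design$wells$row[i], design$wells$col[i])
}

# Internal: a pseudo bi-dimensional design whose libraries are an arbitrary
# subset of real pools, with per-library individual counts fixed externally
# (used by the split-pool false-positive procedure, where every pseudo
# library is an original column pool and keeps that pool's i_l).
pseudo_design <- function(row_libs, col_libs, i_l) {
  n_rows <- length(row_libs); n_cols <- length(col_libs)
  stopifnot(n_rows >= 1, n_cols >= 1, length(i_l) == n_rows + n_cols)
  libraries <- data.frame(
    library = c(row_libs, col_libs),
    type    = rep(c("row", "col"), c(n_rows, n_cols)),
    i_l     = i_l, stringsAsFactors = FALSE
  )
  grid <- expand.grid(col_idx = seq_len(n_cols), row_idx = seq_len(n_rows))
  wells <- data.frame(
    well    = sprintf("(%s,%s)", row_libs[grid$row_idx], col_libs[grid$col_idx]),
    row     = row_libs[grid$row_idx],
    col     = col_libs[grid$col_idx],
    row_idx = grid$row_idx,
    col_idx = as.integer(n_rows + grid$col_idx),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_rows = n_rows, n_cols = n_cols, i_well = NA_integer_,
         n_w = n_rows * n_cols, rows = row_libs, cols = col_libs,
         libraries = libraries, wells = wells),
    class = "pool_design"
  )
}
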