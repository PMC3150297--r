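#' Per-position evidence across all libraries
#'
#' The unit the caller consumes: for one reference position, the retained
#' base-call counts of every library in the design, split by strand.
#'
#' @param seqid Reference sequence name.
#' @param pos 1-based position.
#' @param ref Reference base, one of A/C/G/T (anything else marks the
#'   position uncallable).
#' @param n Numeric vector of retained coverage per library, in
#'   \code{design$libraries} order.
#' @param k Matrix (library x base) of base-call counts; columns named
#'   A, C, G, T; rows sum to \code{n}.
#' @param fwd Matrix like \code{k} holding the forward-strand subset of each
#'   count (reverse counts are \code{k - fwd}). Optional; defaults to an even
#'   split for count-only data.
#' @return A \code{position_data} object.
#' @export
position_data <- function(seqid, pos, ref, n, k, fwd = NULL) {
  k <- as.matrix(k)
  stopifnot(ncol(k) == 4L, length(n) == nrow(k))
  colnames(k) <- BASES
  if (is.null(fwd)) fwd <- floor(k / 2)
  fwd <- as.matrix(fwd)
  colnames(fwd) <- BASES
  stopifnot(all(dim(fwd) == dim(k)), all(fwd >= 0), all(fwd <= k))
  if (any(abs(rowSums(k) - n) > 1e-9))
    stop("position_data: per-library counts must sum to coverage n")
  structure(list(seqid = seqid, pos = as.integer(pos), ref = ref,
                 n = as.numeric(n), k = k, fwd = fwd),
            class = "position_data")
}

#' @export
print.position_data <- function(x, ...) {
  cat(sprintf("position_data %s:%d ref=%s, %d libraries, total coverage %g\n",
              x$seqid, x$pos, x$ref, length(x$n), sum(x$n)))
  invisible(x)
}

# Internal fast constructor (no validation) for simulator / hot loops.
new_position_data <- function(seqid, pos, ref, n, k, fwd) {
  structure(list(seqid = seqid, pos = pos, ref = ref, n = n, k = k, fwd = fwd),
            class = "position_data")
}
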