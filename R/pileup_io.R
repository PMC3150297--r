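#' Parse a samtools-style text pileup for one library
#'
#' Reads the classic 6-column pileup ("seq pos ref depth bases quals").
#' Reference-matching calls are encoded '.' (forward) / ',' (reverse),
#' alternate calls as upper/lower-case bases; read-start ('^' plus mapping
#' quality), read-end ('$'), indels ('+n.../-n...') and deletion
#' placeholders ('*', and reference skips '>'/'<') are consumed but never
#' counted -- the model is substitution-only. Each counted or placeholder
#' call consumes one quality character.
#'
#' @param path File path (or connection) of the pileup.
#' @param library Library identifier to stamp on the columns.
#' @param quality_offset ASCII offset of the quality encoding (default 33,
#'   Phred+33).
#' @return A list of library columns; each is a list with \code{library},
#'   \code{seqid}, \code{pos}, \code{ref}, and \code{calls}, a data frame
#'   with \code{base}, \code{fwd} (logical strand) and \code{qual} for every
#'   retained call.
#' @export
read_pileup <- function(path, library, quality_offset = 33) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6)
      stop(sprintf("pileup parse error at line %d: expected 6 fields", i))
    depth <- suppressWarnings(as.integer(f[4]))
    if (is.na(depth))
      stop(sprintf("pileup parse error at line %d: bad depth '%s'", i, f[4]))
    calls <- parse_pileup_bases(f[5], f[6], toupper(f[3]), quality_offset, i)
    list(library = library, seqid = f[1], pos = as.integer(f[2]),
         ref = toupper(f[3]), calls = calls)
  })
}

# Walk the bases string, pairing counted calls (and '*'/'>'/'<'
# placeholders) with quality characters.
parse_pileup_bases <- function(bases, quals, ref, quality_offset, lineno) {
  empty <- data.frame(base = character(0), fwd = logical(0), qual = numeric(0),
                      stringsAsFactors = FALSE)
  if (identical(bases, "*") && identical(quals, "*")) return(empty)
  ch <- strsplit(bases, "")[[1]]
  qv <- if (identical(quals, "*")) integer(0)
        else utf8ToInt(quals) - quality_offset
  base <- character(0); fwd <- logical(0); qual <- numeric(0)
  i <- 1L; qi <- 1L
  take_q <- function() {
    if (qi > length(qv))
      stop(sprintf("pileup parse error at line %d: bases/quals length mismatch",
                   lineno))
    q <- qv[qi]; qi <<- qi + 1L; q
  }
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 == "^") { i <- i + 2L; next }            # '^' + mapping quality
    if (c0 == "$") { i <- i + 1L; next }
    if (c0 == "+" || c0 == "-") {                   # indel: +len seq
      j <- i + 1L
      while (j <= length(ch) && grepl("[0-9]", ch[j])) j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len; next
    }
    if (c0 %in% c("*", ">", "<")) { take_q(); i <- i + 1L; next }
    q <- take_q()
    if (c0 == ".") { base <- c(base, ref); fwd <- c(fwd, TRUE) }
    else if (c0 == ",") { base <- c(base, ref); fwd <- c(fwd, FALSE) }
    else if (c0 %in% BASES) { base <- c(base, c0); fwd <- c(fwd, TRUE) }
    else if (toupper(c0) %in% BASES) { base <- c(base, toupper(c0)); fwd <- c(fwd, FALSE) }
    else { i <- i + 1L; next }                      # N/n: uncounted
    qual <- c(qual, q)
    i <- i + 1L
  }
  if (qi <= length(qv))
    stop(sprintf("pileup parse error at line %d: bases/quals length mismatch",
                 lineno))
  data.frame(base = base, fwd = fwd, qual = qual, stringsAsFactors = FALSE)
}

# Count a parsed column after discarding calls strictly below the cutoff.
count_column <- function(col, cutoff = -Inf) {
  calls <- col$calls[col$calls$qual >= cutoff, , drop = FALSE]
  k <- fwd <- stats::setNames(numeric(4), BASES)
  for (b in BASES) {
    sel <- calls$base == b
    k[b] <- sum(sel)
    fwd[b] <- sum(sel & calls$fwd)
  }
  list(n = sum(k), k = k, fwd = fwd)
}

#' Assemble per-library pileups into per-position data
#'
#' Applies each library's quality cutoff (one sd below the mean reference
#' call quality, per library per gene; see
#' \code{\link{library_quality_cutoff}}), then collates one
#' \code{\link{position_data}} per reference position with one column per
#' design library. Libraries without data at a position contribute
#' zero-count columns. The pileup reference base is cross-checked against
#' the FASTA.
#'
#' @param columns_by_library Named list (library id ->
#'   \code{\link{read_pileup}} result).
#' @param design The \code{pool_design}; all its libraries must appear in
#'   \code{columns_by_library} (possibly with empty column lists).
#' @param reference Named character vector or \code{DNAStringSet} of
#'   reference sequences.
#' @param quality_filter Apply the per-library cutoff (default TRUE).
#' @return List of \code{\link{position_data}} in (sequence, position)
#'   order, covering every reference position. Positions with a non-ACGT
#'   reference base are flagged uncallable via \code{ref}.
#' @export
assemble_positions <- function(columns_by_library, design, reference,
                               quality_filter = TRUE) {
  refs <- stats::setNames(toupper(as.character(reference)), names(reference))
  if (is.null(names(refs))) stop("reference sequences must be named")
  libs <- design$libraries$library
  missing <- setdiff(libs, names(columns_by_library))
  if (length(missing) > 0L)
    stop("no pileup provided for libraries: ", paste(missing, collapse = ", "))
  L <- length(libs)

  # per (library, gene) quality cutoffs
  counts <- list()   # key "lib\rseq\rpos" -> count_column() result
  for (li in seq_len(L)) {
    cols <- columns_by_library[[libs[li]]]
    if (length(cols) == 0L) next
    seqids <- vapply(cols, function(cc) cc$seqid, character(1))
    for (sq in unique(seqids)) {
      sel <- which(seqids == sq)
      refq <- unlist(lapply(cols[sel], function(cc) {
        cc$calls$qual[cc$calls$base == cc$ref]
      }))
      cutoff <- if (!quality_filter || length(refq) == 0L) -Inf
                else library_quality_cutoff(refq)
      for (j in sel) {
        cc <- cols[[j]]
        if (cc$ref %in% BASES && !is.na(match(sq, names(refs)))) {
          fb <- substr(refs[[sq]], cc$pos, cc$pos)
          if (nzchar(fb) && fb %in% BASES && fb != cc$ref)
            stop(sprintf("reference mismatch at %s:%d: pileup %s, FASTA %s",
                         sq, cc$pos, cc$ref, fb))
        }
        counts[[paste(li, sq, cc$pos, sep = "\r")]] <- count_column(cc, cutoff)
      }
    }
  }

  positions <- list()
  for (sq in names(refs)) {
    ref_chars <- strsplit(refs[[sq]], "")[[1]]
    for (p in seq_along(ref_chars)) {
      n <- numeric(L)
      k <- matrix(0, L, 4, dimnames = list(NULL, BASES))
      fwd <- matrix(0, L, 4, dimnames = list(NULL, BASES))
      for (li in seq_len(L)) {
        ct <- counts[[paste(li, sq, p, sep = "\r")]]
        if (is.null(ct)) next
        n[li] <- ct$n; k[li, ] <- ct$k; fwd[li, ] <- ct$fwd
      }
      positions[[length(positions) + 1L]] <-
        new_position_data(sq, p, ref_chars[p], n, k, fwd)
    }
  }
  positions
}

#' Write mutation calls as TSV
#'
#' @param calls Ranked calls data frame (see \code{\link{select_calls}}).
#' @param path Destination file.
#' @return Invisibly, the path.
#' @export
write_calls <- function(calls, path) {
  cols <- c("seqid", "pos", "ref", "alt", "row_library", "column_library",
            "well", "t", "F", "rank")
  out <- calls[, intersect(cols, names(calls)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write mutation calls as minimal VCF
#'
#' Emits VCF 4.2 with the pool/well attribution in INFO keys ROWPOOL,
#' COLPOOL, WELL, POST and F.
#'
#' @inheritParams write_calls
#' @export
write_calls_vcf <- function(calls, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=ROWPOOL,Number=1,Type=String,Description=\"Row pool library\">",
           "##INFO=<ID=COLPOOL,Number=1,Type=String,Description=\"Column pool library\">",
           "##INFO=<ID=WELL,Number=1,Type=String,Description=\"Carrier well\">",
           "##INFO=<ID=POST,Number=1,Type=Float,Description=\"Posterior probability\">",
           "##INFO=<ID=F,Number=1,Type=Float,Description=\"Log-odds score\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls) == 0L) character(0) else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tROWPOOL=%s;COLPOOL=%s;WELL=%s;POST=%.6g;F=%.4f",
    calls$seqid, calls$pos, calls$ref, calls$alt, calls$row_library,
    calls$column_library, gsub("[(),]", "", calls$well), calls$t, calls$F)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated positions as per-library pileup files
#'
#' Inverse of the parse path: one 6-column pileup file per design library,
#' with constant base quality. Round-trips losslessly through
#' \code{\link{read_pileup}} / \code{\link{assemble_positions}}.
#'
#' @param positions List of \code{\link{position_data}}.
#' @param design The \code{pool_design}.
#' @param dir Output directory (created if needed).
#' @param quality Constant Phred score to stamp on calls.
#' @param quality_offset Encoding offset (default 33).
#' @return Named vector of file paths, one per library.
#' @export
write_pileups <- function(positions, design, dir, quality = 31,
                          quality_offset = 33) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  libs <- design$libraries$library
  qc <- intToUtf8(quality + quality_offset)
  paths <- stats::setNames(file.path(dir, paste0(libs, ".pileup")), libs)
  con <- lapply(paths, file, open = "wt")
  on.exit(lapply(con, close), add = TRUE)
  for (p in positions) {
    for (li in seq_along(libs)) {
      n <- p$n[li]
      parts <- character(0)
      for (b in BASES) {
        nf <- p$fwd[li, b]; nr <- p$k[li, b] - nf
        sym_f <- if (b == p$ref) "." else b
        sym_r <- if (b == p$ref) "," else tolower(b)
        parts <- c(parts, strrep(sym_f, nf), strrep(sym_r, nr))
      }
      bases <- paste(parts, collapse = "")
      line <- sprintf("%s\t%d\t%s\t%d\t%s\t%s", p$seqid, p$pos, p$ref, n,
                      if (n > 0) bases else "*",
                      if (n > 0) strrep(qc, n) else "*")
      writeLines(line, con[[li]])
    }
  }
  paths
}

#' Read reference sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reference sequences to FASTA
#'
#' @param refs Named character vector.
#' @param path Destination.
#' @return Invisibly, the path.
#' @export
write_reference <- function(refs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), path)
  invisible(path)
}
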