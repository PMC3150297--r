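pileup_file <- function(lines) {
  f <- tempfile(fileext = ".pileup")
  writeLines(lines, f)
  f
}

test_that("pileup grammar parses calls, strands and qualities", {
  cols <- read_pileup(pileup_file("g1\t100\tC\t5\t..,,T\tIIIII"), "R1")
  expect_length(cols, 1)
  cc <- cols[[1]]
  expect_equal(cc$seqid, "g1")
  expect_equal(cc$pos, 100L)
  ct <- camba:::count_column(cc)
  expect_equal(ct$n, 5)
  expect_equal(unname(ct$k["C"]), 4)
  expect_equal(unname(ct$fwd["C"]), 2)
  expect_equal(unname(ct$k["T"]), 1)
  expect_equal(unname(ct$fwd["T"]), 1)
  expect_equal(cc$calls$qual, rep(40, 5))   # 'I' = 73 - 33
})

test_that("read starts, ends, indels and deletions are consumed uncounted", {
  # ^X. starts a read with mapping quality, $ ends one, +2AA inserts,
  # * is a deletion placeholder consuming a quality
  cols <- read_pileup(pileup_file("g1\t7\tG\t6\t^I.$,a+2AAT*.\tIIJIII"), "R1")
  ct <- camba:::count_column(cols[[1]])
  expect_equal(ct$n, 5)            # '*' not counted
  expect_equal(unname(ct$k["G"]), 3)
  expect_equal(unname(ct$fwd["G"]), 2)
  expect_equal(unname(ct$k["A"]), 1)   # reverse-strand 'a'
  expect_equal(unname(ct$fwd["A"]), 0)
  expect_equal(unname(ct$k["T"]), 1)
})

test_that("empty streams, zero-depth lines and malformed input behave", {
  expect_length(read_pileup(pileup_file(character(0)), "R1"), 0)
  cols <- read_pileup(pileup_file("g1\t5\tA\t0\t*\t*"), "R1")
  expect_equal(camba:::count_column(cols[[1]])$n, 0)
  expect_error(read_pileup(pileup_file("g1\t5\tA\t3\t...\tII"), "R1"),
               "mismatch")
  expect_error(read_pileup(pileup_file("g1\t5\tA\t3"), "R1"), "6 fields")
})

test_that("counts equal a naive character-frequency oracle", {
  set.seed(4)
  for (rep_i in 1:20) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    n <- sample(0:40, 1)
    syms <- sample(c(".", ",", "A", "a", "T", "t", "G", "g", "C", "c"), n,
                   replace = TRUE)
    syms <- syms[toupper(syms) != ref]   # alternates must differ from ref
    line <- sprintf("g\t1\t%s\t%d\t%s\t%s", ref, length(syms),
                    paste(syms, collapse = ""),
                    strrep("I", length(syms)))
    ct <- camba:::count_column(read_pileup(pileup_file(line), "L")[[1]])
    expect_equal(ct$n, length(syms))
    for (b in c("A", "C", "G", "T")) {
      want <- if (b == ref) sum(syms %in% c(".", ","))
      else sum(syms %in% c(b, tolower(b)))
      expect_equal(unname(ct$k[b]), want)
    }
  }
})

test_that("simulated data round-trips through pileup files", {
  sim <- small_sim(7, n_rows = 2, n_cols = 3, len = 15, coverage = 40,
                   n_planted = 1)
  dir <- tempfile("pileups")
  write_pileups(sim$positions, sim$design, dir, quality = 31)
  libs <- sim$design$libraries$library
  cols <- lapply(libs, function(l) {
    read_pileup(file.path(dir, paste0(l, ".pileup")), l)
  })
  names(cols) <- libs
  refs <- stats::setNames(sim$spec$references, names(sim$spec$references))
  back <- assemble_positions(cols, sim$design, refs)
  expect_length(back, length(sim$positions))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$n, sim$positions[[i]]$n)
    expect_equal(back[[i]]$k, sim$positions[[i]]$k)
    expect_equal(back[[i]]$fwd, sim$positions[[i]]$fwd)
  }
})

test_that("assembly spans all reference positions and flags gaps as zero", {
  d <- build_design(1, 1, 2)
  refs <- c(gA = "ACG", gB = paste(rep("A", 5), collapse = ""))
  colsR <- read_pileup(pileup_file(c("gA\t1\tA\t2\t..\tII",
                                     "gA\t3\tG\t1\t,\tI")), "R1")
  colsC <- read_pileup(pileup_file("gB\t2\tA\t2\t.,\tII"), "C1")
  pos <- assemble_positions(list(R1 = colsR, C1 = colsC), d, refs)
  expect_length(pos, 8)   # 3 + 5, grouped by gene
  expect_equal(pos[[2]]$n, c(0, 0))            # gA:2 absent everywhere
  expect_equal(pos[[1]]$n, c(2, 0))            # gA:1 only in R1
  expect_equal(unname(pos[[5]]$k[2, "A"]), 2)  # gB:2 in C1
  # reference mismatch is a consistency error
  bad <- read_pileup(pileup_file("gA\t1\tC\t1\t.\tI"), "C1")
  expect_error(assemble_positions(list(R1 = colsR, C1 = bad), d, refs),
               "mismatch")
  expect_error(assemble_positions(list(R1 = colsR), d, refs), "no pileup")
})

test_that("call tables round-trip as TSV and render as VCF", {
  calls <- data.frame(seqid = "g1", pos = c(7L, 3L), ref = "G", alt = "A",
                      row_library = c("R1", "R2"), column_library = "C1",
                      well = c("(R1,C1)", "(R2,C1)"), t = c(0.99, 0.8),
                      F = c(4.6, 1.39), rank = 1:2, stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_calls(calls, f)
  back <- utils::read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$F, calls$F)
  expect_equal(nrow(utils::read.delim(write_calls(calls[0, ], f))), 0)

  v <- tempfile(fileext = ".vcf")
  write_calls_vcf(calls, v)
  lines <- readLines(v)
  expect_equal(sum(!startsWith(lines, "#")), 2)
  expect_match(lines[length(lines)], "ROWPOOL=R2;COLPOOL=C1;WELL=R2C1")
})
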