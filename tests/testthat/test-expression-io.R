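test_that("expression TSV reading enforces invariants and round-trips", {
  x <- toy_expr(is_log2 = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, f)
  y <- read_expression(f, is_log2 = FALSE)
  expect_s3_class(y, "expr_mat")
  expect_identical(dim(y), c(3L, 4L))
  expect_equal(unclass(y)[, ], unclass(x)[, ])
  expect_false(is_log2(y))

  # write(read(f)) reproduces the file byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression(y, f2)
  expect_identical(readLines(f), readLines(f2))

  # duplicated feature row id names the offender
  writeLines(c("feature_id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), f)
  expect_error(read_expression(f), "gA")

  # non-numeric cell names row and column
  writeLines(c("feature_id\ts1\ts2", "gA\t1\tx", "gB\t3\t4"), f)
  expect_error(read_expression(f), "gA.*s2")
})

test_that("expression_matrix rejects malformed input", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s3_class(expression_matrix(m), "expr_mat")
  m_na <- m; m_na[1, 1] <- NA
  expect_error(expression_matrix(m_na), "non-finite")
  expect_error(expression_matrix(m[, 1, drop = FALSE]), "two samples")
  m_dup <- m; colnames(m_dup) <- c("s1", "s1")
  expect_error(expression_matrix(m_dup), "duplicate sample")
})

test_that("log2_transform follows the definition and guards its domain", {
  x <- toy_expr(matrix(c(8, 8, 0, 0, 1, 3), 3, 2, byrow = TRUE),
                is_log2 = FALSE)
  y <- log2_transform(x, offset = 1)
  expect_true(is_log2(y))
  expect_equal(unname(unclass(y)[1, ]), c(log2(9), log2(9)))
  expect_equal(unname(unclass(y)[2, ]), c(0, 0))       # log2(0 + 1) = 0
  z <- log2_transform(toy_expr(matrix(8, 2, 2), is_log2 = FALSE), offset = 0)
  expect_equal(unname(unclass(z)[1, 1]), 3)            # log2(8) = 3
  expect_error(log2_transform(y), "already")
  expect_error(log2_transform(x, offset = 0), "nonpositive")
})

test_that("GMT parsing is strict and write/read round-trips", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("S1\tdesc\tA\tB", "S2\tna\tC\tD\tE"), f)
  gs <- read_gmt(f)
  expect_named(gs, c("S1", "S2"))
  expect_identical(gs$S1, c("A", "B"))

  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, f2)
  expect_identical(read_gmt(f2), read_gmt(f))

  writeLines(c("S1\tdesc\tA", "EMPTY\tdesc"), f)
  expect_error(read_gmt(f), "line 2")
  expect_error(write_gmt(list(S = character(0)), f2), "empty")
})

test_that("RNK writing sorts descending with stable ties and rejects NaN", {
  f <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(c(B = -1, A = 2), f)
  expect_identical(readLines(f), c("A\t2", "B\t-1"))

  # ties broken by feature id, and a planted ranking matches a hand sort
  out <- write_rnk(c(zeta = 1, alpha = 1, mid = 1.5, top = 3), f)
  expect_identical(out$feature, c("top", "mid", "alpha", "zeta"))
  expect_error(write_rnk(c(A = NaN, B = 1), f), "non-finite")
})

test_that("clinical tables validate coding and pair structure", {
  tbl <- simple_clinical(5)
  expect_s3_class(tbl, "clinical_tbl")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_clinical(tbl, f)
  expect_equal(read_clinical(f)$os_time, tbl$os_time)

  bad <- data.frame(sample_id = c("a", "b"), os_time = c(1, -2),
                    os_event = c(0, 1), tissue = "tumor")
  expect_error(clinical_table(bad), "os_time")
  bad$os_time <- c(1, 2); bad$os_event <- c(0, 2)
  expect_error(clinical_table(bad), "os_event")
  # pair_id must link one tumor to one normal
  paired <- data.frame(sample_id = c("t1", "t2"), os_time = 1, os_event = 0,
                       tissue = c("tumor", "tumor"), pair_id = "p1")
  expect_error(clinical_table(paired), "pair_id")
})

test_that("align_samples intersects, preserves order, and is idempotent", {
  x <- toy_expr()
  cl <- simple_clinical(4)
  cl$sample_id <- c("s2", "s3", "s9", "s10")
  al <- suppressMessages(align_samples(x, cl))
  expect_identical(colnames(al$expr), c("s2", "s3"))
  expect_identical(al$clinical$sample_id, c("s2", "s3"))
  expect_identical(al$dropped_expr, 2L)
  al2 <- align_samples(al$expr, al$clinical)
  expect_identical(unclass(al2$expr)[, ], unclass(al$expr)[, ])
  expect_identical(al2$dropped_expr + al2$dropped_clinical, 0L)

  cl$sample_id <- c("x1", "x2", "x3", "x4")
  expect_error(align_samples(x, cl), "no overlap")
})

test_that("probe collapsing keeps the highest-mean probe per gene", {
  m <- matrix(c(1, 1, 5, 5, 2, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  x <- expression_matrix(m, is_log2 = TRUE)
  col <- collapse_by_max_mean(x, c(p1 = "GENE", p2 = "GENE", p3 = "OTHER"))
  expect_identical(sort(rownames(col)), c("GENE", "OTHER"))
  expect_equal(unname(unclass(col)["GENE", ]), c(5, 5))
})
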