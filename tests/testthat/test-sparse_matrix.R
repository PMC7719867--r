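test_that("dense_to_coo enumerates nonzeros in row-major order", {
  z <- dense_to_coo(matrix(0L, 3, 4))
  expect_identical(length(z$row), 0L)
  expect_identical(z$n_rows, 3L)
  expect_identical(z$n_cols, 4L)

  m <- matrix(c(0L, 1L, 3L, 0L), 2, 2)  # [[0,3],[1,0]]
  coo <- dense_to_coo(m)
  expect_identical(coo$row, c(0L, 1L))
  expect_identical(coo$col, c(1L, 0L))
  expect_identical(coo$value, c(3L, 1L))

  id3 <- dense_to_coo(diag(3))
  expect_identical(id3$row, 0:2)
  expect_identical(id3$col, 0:2)
  expect_identical(id3$value, c(1L, 1L, 1L))
})

test_that("compress_rows builds adjacent index-pointer pairs", {
  expect_equal(compress_rows(c(0, 0, 1, 3), 4), c(0, 2, 3, 3, 4))
  expect_equal(compress_rows(integer(0), 3), c(0, 0, 0, 0))
  expect_equal(compress_rows(0:2, 3), c(0, 1, 2, 3))
  expect_error(compress_rows(c(1, 0), 2), "sorted")
  expect_error(compress_rows(c(0, 5), 3), "range")
})

test_that("compress_rows equals the cumulative per-row histogram", {
  set.seed(21)
  for (rep in 1:30) {
    n_rows <- sample(1:20, 1)
    r <- sort(sample(0:(n_rows - 1), sample(0:40, 1), replace = TRUE))
    p <- compress_rows(r, n_rows)
    hist <- vapply(0:(n_rows - 1), function(i) sum(r == i), numeric(1))
    expect_equal(p, c(0, cumsum(hist)))
    expect_equal(p[n_rows + 1], length(r))
  }
})

test_that("coo + row compression reconstructs random dense matrices", {
  set.seed(22)
  for (rep in 1:40) {
    n_rows <- sample(1:50, 1)
    n_cols <- sample(1:80, 1)
    m <- matrix(sample(0:5, n_rows * n_cols, replace = TRUE,
                       prob = c(0.7, rep(0.06, 5))), n_rows, n_cols)
    coo <- dense_to_coo(m)
    p <- compress_rows(coo$row, n_rows)
    back <- reconstruct_dense(p, coo$col, coo$value, n_rows, n_cols)
    expect_identical(unname(back), unname(m * 1))
  }
})

test_that("CSR layout agrees with Matrix's dgRMatrix on random input", {
  set.seed(23)
  for (rep in 1:10) {
    m <- matrix(sample(0:3, 30 * 12, replace = TRUE, prob = c(.8, .1, .05, .05)),
                30, 12)
    csr <- csr_from_dense(m)
    ref <- methods::as(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                   "generalMatrix"), "RsparseMatrix")
    expect_equal(csr$p, as.numeric(ref@p))
    expect_identical(csr$j, ref@j)
    expect_equal(csr$x, as.numeric(ref@x))
  }
})

test_that("build_count_matrix tallies domain counts per genome", {
  g1 <- make_hits("g1p1", c("PF00001.1", "PF00001.1", "PF00002.2"))
  g2 <- make_hits("g2p1", c("PF00002.2", "PF00002.2", "PF00002.2"))
  mf <- read_manifest(write_genome_set(list(g1 = g1, g2 = g2)))
  m <- build_domain_matrix(mf)
  expect_identical(get_rows(m), c("g1", "g2"))
  expect_identical(get_columns(m), c("PF00001", "PF00002"))
  expect_identical(unname(as.matrix(m)),
                   matrix(c(2, 0, 1, 3), 2, 2))
})

test_that("a genome with zero hits keeps its all-zero row", {
  g1 <- make_hits("g1p1", "PF00001")
  g2 <- make_hits(character(0), character(0))
  mf <- read_manifest(write_genome_set(list(g1 = g1, g2 = g2)))
  m <- build_domain_matrix(mf)
  expect_identical(dim(m), c(2L, 1L))
  expect_equal(m$p, c(0, 1, 1))
  expect_equal(unname(as.matrix(m))[2, ], 0)
})

test_that("architecture mode yields one column per architecture string", {
  tcdb <- make_hits("prot1", c("PF12918", "PF12919", "PF11713", "PF12920",
                               "PF19127", "PF19127"))
  mf <- read_manifest(write_genome_set(list(gA = tcdb)))
  m <- build_architecture_matrix(mf)
  expect_identical(dim(m), c(1L, 1L))
  expect_identical(get_columns(m),
                   "PF12918_PF12919_PF11713_PF12920_PF19127_PF19127")
  expect_equal(as.matrix(m)[1, 1], 1)
})

test_that("build errors name the offending genome", {
  mf <- data.frame(genome_id = "gX", path = tempfile(),
                   stringsAsFactors = FALSE)
  expect_error(build_domain_matrix(mf), "gX")
})

test_that("binarize flattens values, is idempotent, preserves pattern", {
  m <- csr_from_dense(matrix(c(2, 0, 0, 3), 2, 2))
  b <- binarize(m)
  expect_true(b$is_binary)
  expect_identical(unname(as.matrix(b)), unname(diag(2)))
  expect_identical(binarize(b), b)
  expect_identical(b$p, m$p)
  expect_identical(b$j, m$j)

  e <- binarize(csr_from_dense(matrix(0, 0, 0)))
  expect_identical(dim(e), c(0L, 0L))
})

test_that("save/load round trip is exact, including protein store", {
  set.seed(24)
  for (rep in 1:8) {
    n_rows <- sample(0:15, 1)
    n_cols <- sample(1:20, 1)
    d <- matrix(sample(0:4, n_rows * n_cols, replace = TRUE), n_rows, n_cols)
    m <- csr_from_dense(d)
    folder <- tempfile("mat")
    save_matrix(m, folder)
    expect_same_csr(load_matrix(folder), m)
  }

  g1 <- make_hits("g1p1", c("PF00001", "PF00002"))
  mf <- read_manifest(write_genome_set(list(g1 = g1)))
  m <- build_domain_matrix(mf, keep = TRUE)
  folder <- tempfile("mat")
  save_matrix(m, folder)
  back <- load_matrix(folder)
  expect_same_csr(back, m)
  expect_identical(attr(back, "protein_index"), attr(m, "protein_index"))
})

test_that("0x0 matrix survives the round trip", {
  m <- csr_from_dense(matrix(0, 0, 0))
  folder <- tempfile("mat")
  save_matrix(m, folder)
  expect_same_csr(load_matrix(folder), m)
})

test_that("load_binary_matrix equals binarize of load_matrix", {
  m <- csr_from_dense(matrix(c(0, 2, 5, 1), 2, 2))
  folder <- tempfile("mat")
  save_matrix(m, folder)
  expect_same_csr(load_binary_matrix(folder), binarize(load_matrix(folder)))
})

test_that("incomplete or foreign folders are rejected by name", {
  m <- csr_from_dense(matrix(1, 1, 1))
  folder <- tempfile("mat")
  save_matrix(m, folder)
  file.remove(file.path(folder, "cols.txt"))
  expect_error(load_matrix(folder), "cols.txt")

  folder2 <- tempfile("mat")
  save_matrix(m, folder2)
  meta <- readLines(file.path(folder2, "metadata.dcf"))
  writeLines(sub("format_version: 1", "format_version: 99", meta),
             file.path(folder2, "metadata.dcf"))
  expect_error(load_matrix(folder2), "version")

  expect_error(save_matrix(m, folder2), "overwrite")
  expect_silent(save_matrix(m, folder2, overwrite = TRUE))
})
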