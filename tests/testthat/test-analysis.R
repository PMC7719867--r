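bin_fixture <- function(d) binarize(csr_from_dense(d))

test_that("row and column labels come back in matrix order", {
  d <- matrix(c(1, 0, 0, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("PF1", "PF2")))
  m <- csr_from_dense(d)
  expect_identical(get_rows(m), c("g1", "g2"))
  expect_identical(get_columns(m), c("PF1", "PF2"))

  e <- csr_from_dense(matrix(0, 0, 0))
  expect_identical(get_rows(e), character(0))

  folder <- tempfile()
  save_matrix(m, folder)
  expect_identical(get_rows(load_matrix(folder)), c("g1", "g2"))
  expect_identical(get_columns(load_matrix(folder)), c("PF1", "PF2"))
})

test_that("sum_rows and sum_columns match dense sums", {
  d <- matrix(c(1, 1, 0, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("PF1", "PF2")))
  m <- bin_fixture(d)
  expect_equal(sum_rows(m)$row_sum, c(1, 2))
  expect_equal(sum_columns(m)$col_sum, c(2, 1))

  expect_equal(sum_rows(m, list_col = character(0))$row_sum, c(0, 0))
  expect_equal(sum_columns(m, list_row = "g1", list_col = "PF1")$col_sum, 1)

  cnt <- csr_from_dense(matrix(3, 1, 1, dimnames = list("g1", "tox")))
  expect_equal(sum_columns(cnt, list_row = "g1", list_col = "tox")$col_sum, 3)
  expect_equal(sum_rows(cnt)$row_sum, 3)
})

test_that("unknown labels are reported by name", {
  m <- bin_fixture(matrix(1, 1, 1, dimnames = list("g1", "PF1")))
  expect_error(sum_rows(m, list_row = "nope"), "nope")
  expect_error(sum_columns(m, list_col = "missing"), "missing")
  expect_error(cal_core(m, list_col = "missing"), "missing")
})

test_that("total mass is conserved between row and column sums", {
  set.seed(31)
  for (rep in 1:10) {
    d <- matrix(sample(0:4, 12 * 9, replace = TRUE), 12, 9)
    dimnames(d) <- list(sprintf("g%d", 1:12), sprintf("PF%d", 1:9))
    m <- csr_from_dense(d)
    expect_equal(sum(sum_rows(m)$row_sum), sum(sum_columns(m)$col_sum))
    expect_equal(sum(sum_rows(m)$row_sum), sum(d))
  }
})

test_that("cal_core keeps the 95% boundary inclusive", {
  # feature A present in 19/20 genomes, feature B in 18/20
  d <- cbind(A = c(rep(1, 19), 0), B = c(rep(1, 18), 0, 0))
  rownames(d) <- sprintf("g%02d", 1:20)
  m <- bin_fixture(d)
  res <- cal_core(m, cutoff = 0.95)
  expect_identical(res$col_name, "A")
  expect_identical(res$genome_count, 19)
  expect_equal(res$fraction, 0.95)
})

test_that("cal_core is exact at rational boundaries for many n", {
  # count/n mathematically equal to the cutoff must always be retained
  for (n in c(20, 40, 60, 100, 140)) {
    d <- matrix(c(rep(1, n * 0.95), rep(0, n * 0.05)), ncol = 1,
                dimnames = list(sprintf("g%d", 1:n), "F"))
    m <- bin_fixture(d)
    expect_identical(cal_core(m, cutoff = 0.95)$col_name, "F")
    just_below <- d
    just_below[1, 1] <- 0
    expect_identical(nrow(cal_core(bin_fixture(just_below), cutoff = 0.95)),
                     0L)
  }
})

test_that("cal_core spans its cutoff range correctly", {
  set.seed(32)
  d <- matrix(rbinom(30 * 15, 1, 0.5), 30, 15,
              dimnames = list(sprintf("g%d", 1:30), sprintf("PF%d", 1:15)))
  m <- bin_fixture(d)
  expect_identical(cal_core(m, cutoff = 0)$col_name, get_columns(m))
  strict <- cal_core(m, cutoff = 1)$col_name
  expect_identical(strict, colnames(d)[colSums(d) == 30])

  # antitone in cutoff
  cuts <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  res <- lapply(cuts, function(ct) cal_core(m, cutoff = ct)$col_name)
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(res[[i + 1]] %in% res[[i]]))
  }
})

test_that("cal_core refuses count matrices and empty genome lists", {
  cnt <- csr_from_dense(matrix(2, 1, 1, dimnames = list("g1", "PF1")))
  expect_error(cal_core(cnt), "binary")
  m <- binarize(cnt)
  expect_error(cal_core(m, list_row = character(0)), "empty")
  expect_error(cal_core(m, cutoff = 1.5), "cutoff")
})

test_that("denominator is the queried genome list, not all rows", {
  d <- matrix(c(1, 0, 0, 0), 4, 1, dimnames = list(sprintf("g%d", 1:4), "F"))
  m <- bin_fixture(d)
  expect_identical(nrow(cal_core(m, cutoff = 0.95)), 0L)
  res <- cal_core(m, list_row = "g1", cutoff = 0.95)
  expect_identical(res$col_name, "F")
  expect_equal(res$fraction, 1)
})

test_that("get_protein_ids looks up the store and writes the TSV", {
  g1 <- rbind(make_hits("p7", "PF04542.5"), make_hits("p9", "PF00001.1"))
  g2 <- make_hits("q1", "PF00001.2")
  mf <- read_manifest(write_genome_set(list(g1 = g1, g2 = g2)))
  m <- build_domain_matrix(mf, keep = TRUE)
  out <- tempfile()
  res <- get_protein_ids(m, list_col = "PF04542", output = out)
  expect_identical(nrow(res), 1L)
  expect_identical(unlist(res[1, ], use.names = FALSE),
                   c("g1", "PF04542", "p7"))
  expect_identical(readLines(out), "g1\tPF04542\tp7")

  # feature absent from a queried genome yields no row for it
  res2 <- get_protein_ids(m, list_row = "g2", list_col = "PF04542")
  expect_identical(nrow(res2), 0L)
})

test_that("architecture queries return only exact-architecture proteins", {
  bont <- make_hits("ntx1", c("PF01742", "PF07952", "PF07953", "PF07951"))
  partial <- make_hits("ntx2", c("PF01742", "PF07952"))
  mf <- read_manifest(write_genome_set(list(gb = rbind(bont, partial))))
  m <- build_architecture_matrix(mf, keep = TRUE)
  res <- get_protein_ids(m, list_col = "PF01742_PF07952_PF07953_PF07951")
  expect_identical(res$protein_id, "ntx1")
})

test_that("get_protein_ids requires the keep-time store", {
  m <- build_domain_matrix(
    read_manifest(write_genome_set(list(g1 = make_hits("p1", "PF00001")))))
  expect_error(get_protein_ids(m), "keep")
})

test_that("analysis on CSR equals analysis on the densified matrix", {
  set.seed(33)
  for (rep in 1:15) {
    n_rows <- sample(2:40, 1)
    n_cols <- sample(2:60, 1)
    d <- matrix(rbinom(n_rows * n_cols, 1, runif(1, 0.05, 0.6)),
                n_rows, n_cols,
                dimnames = list(sprintf("g%03d", 1:n_rows),
                                sprintf("PF%05d", 1:n_cols)))
    m <- bin_fixture(d)
    rows <- sample(rownames(d), sample(1:n_rows, 1))
    cols <- sample(colnames(d), sample(1:n_cols, 1))
    cutoff <- sample(c(0, 0.25, 0.5, 0.77, 0.95, 1), 1)
    expect_equal(sum_rows(m, rows, cols),
                 naive_oracle(d, "sum_rows", rows, cols))
    expect_equal(sum_columns(m, rows, cols),
                 naive_oracle(d, "sum_columns", rows, cols))
    expect_equal(cal_core(m, rows, cols, cutoff),
                 naive_oracle(d, "core", rows, cols, cutoff))
  }
})
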