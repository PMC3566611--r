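make_expr <- function(male_counts, female_counts) {
  # one gene per row; columns are male then female samples
  m <- cbind(male_counts, female_counts)
  rownames(m) <- sprintf("g%02d", seq_len(nrow(m)))
  colnames(m) <- c(sprintf("m%d", seq_len(ncol(male_counts))),
                   sprintf("f%d", seq_len(ncol(female_counts))))
  expression_matrix(m, rep(c("male", "female"),
                           c(ncol(male_counts), ncol(female_counts))))
}

test_that("global read bias matches per-sex average totals", {
  # symmetric totals
  e <- make_expr(matrix(c(200, 200, 100, 300), nrow = 2),
                 matrix(c(200, 200, 100, 300), nrow = 2))
  expect_equal(global_read_bias(e), 0)

  # one male sample total 800, one female total 200 -> log2(4) = 2
  e <- make_expr(matrix(c(500, 300), nrow = 2),
                 matrix(c(150, 50), nrow = 2))
  expect_equal(global_read_bias(e), 2)

  # male totals {100, 300} vs female {200, 200}: equal averages
  e <- make_expr(matrix(c(40, 60, 120, 180), nrow = 2),
                 matrix(c(80, 120, 80, 120), nrow = 2))
  expect_equal(global_read_bias(e), 0)

  # zero depth in one sex is undefined
  e0 <- expression_matrix(
    matrix(c(5, 0), nrow = 1, dimnames = list("g", c("m1", "f1"))),
    c("male", "female"))
  expect_error(global_read_bias(e0), "zero total depth")
})

test_that("bias table reproduces the depth-weighted worked example", {
  # male totals {100, 300}, gene counts {10, 60}; female totals {200, 200},
  # gene counts {5, 5}: w_m = {0.25, 0.75}, Nbar_m = 47.5, Nbar_f = 5, B = 0
  m <- rbind(gA = c(10, 60, 5, 5),
             rest = c(90, 240, 195, 195))
  e <- expression_matrix(
    `dimnames<-`(m, list(rownames(m), c("m1", "m2", "f1", "f2"))),
    c("male", "male", "female", "female"))
  res <- compute_bias_table(e)
  expect_equal(res$intermediates$weights$male, c(m1 = 0.25, m2 = 0.75))
  expect_equal(res$intermediates$weighted_means$male[1], 47.5)
  expect_equal(res$intermediates$weighted_means$female[1], 5)
  expect_equal(res$intermediates$global_read_bias, 0)
  expect_equal(res$bias$bias[res$bias$gene == "gA"], log2(9.5))
})

test_that("all-zero genes are discarded and one-sex genes hit the cap", {
  m <- rbind(const = c(50, 50, 50, 50),
             male_only = c(40, 40, 0, 0),
             female_only = c(0, 0, 40, 40),
             silent = c(0, 0, 0, 0))
  colnames(m) <- c("m1", "m2", "f1", "f2")
  e <- expression_matrix(m, c("male", "male", "female", "female"))
  res <- compute_bias_table(e)
  expect_setequal(res$bias$gene, c("const", "male_only", "female_only"))
  b <- setNames(res$bias$bias, res$bias$gene)
  expect_equal(unname(b["const"]), 0)
  expect_equal(unname(b["male_only"]), 10)
  expect_equal(unname(b["female_only"]), -10)
  expect_true(all(res$bias$bias >= -10 & res$bias$bias <= 10))
})

test_that("bias table size equals the number of expressed genes", {
  set.seed(42)
  for (i in 1:20) {
    e <- random_expr(n_genes = 15, zero_frac = 0.3)
    res <- compute_bias_table(e)
    expect_identical(nrow(res$bias), sum(rowSums(e$counts) > 0))
  }
})

test_that("bias is invariant to global count scaling and antisymmetric under sex swap", {
  set.seed(7)
  for (i in 1:20) {
    e <- random_expr()
    b <- compute_bias_table(e)$bias

    scaled <- expression_matrix(e$counts * 3.7, e$sample_sex)
    expect_equal(compute_bias_table(scaled)$bias$bias, b$bias)

    swapped_sex <- ifelse(e$sample_sex == "male", "female", "male")
    names(swapped_sex) <- names(e$sample_sex)
    swapped <- expression_matrix(e$counts, swapped_sex)
    expect_equal(compute_bias_table(swapped)$bias$bias, -b$bias)
  }
})

test_that("implementation agrees with the loop-based direct evaluation", {
  set.seed(11)
  for (i in 1:30) {
    e <- random_expr(n_genes = sample(5:50, 1),
                     n_male = sample(1:4, 1), n_female = sample(1:4, 1))
    got <- compute_bias_table(e)$bias
    want <- oracle_bias(e$counts, e$sample_sex)
    expect_equal(setNames(got$bias, got$gene), want, tolerance = 1e-12)
  }
})

test_that("classification follows the threshold rules at boundaries", {
  s4 <- bias_scheme(2)        # four-fold window, no gap
  expect_identical(classify_bias(c(2.5, 2, 0, -2, -2.5), s4),
                   c("male", "unbiased", "unbiased", "unbiased", "female"))

  s32 <- bias_scheme(5, 1)    # stringent conflict scheme with a gap
  expect_identical(classify_bias(c(6, 5, 3, 1, 0, -1.5, -6), s32),
                   c("male", "unclassified", "unclassified", "unbiased",
                     "unbiased", "unclassified", "female"))

  expect_error(bias_scheme(0), "positive")
  expect_error(bias_scheme(2, 3), "<=")
  expect_error(classify_bias(Inf, s4), "finite")
})

test_that("bias tables round-trip through the two-column file dialect", {
  tab <- data.frame(gene = c("FBgn1", "FBgn2", "FBgn3"),
                    bias = c(-10, 0.125, 3.25), stringsAsFactors = FALSE)
  class(tab) <- c("sex_bias_table", "data.frame")
  path <- withr::local_tempfile(fileext = ".txt")
  write_bias_table(tab, path)
  back <- read_bias_table(path)
  expect_equal(back$gene, tab$gene)
  expect_equal(back$bias, tab$bias)
})

test_that("count tables and sample sheets round-trip", {
  e <- random_expr(n_genes = 8)
  counts_path <- withr::local_tempfile(fileext = ".tsv")
  sheet_path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(e, counts_path, sheet_path)
  back <- read_expression(counts_path, sheet_path)
  expect_equal(back$counts, e$counts)
  expect_equal(back$sample_sex, e$sample_sex)
})

test_that("expression matrix validation rejects bad input", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(expression_matrix(m, c("male", "male")),
               "at least one female")
  expect_error(expression_matrix(m, c("male", "cow")), "male")
  m2 <- m; m2[1, 1] <- -1
  expect_error(expression_matrix(m2, c("male", "female")), "negative")
})
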