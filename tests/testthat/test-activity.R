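test_that("pIC50 conversion uses M/1e5 units and rejects non-positives", {
  expect_equal(pic50_from_ic50(1), 5)
  expect_equal(pic50_from_ic50(0.3), 5.523, tolerance = 5e-4)
  expect_equal(pic50_from_ic50(1e5), 0)
  expect_error(pic50_from_ic50(0), "positive")
  expect_error(pic50_from_ic50(-1), "positive")
  # strictly decreasing in IC50
  x <- sort(stats::runif(50, 1e-4, 100))
  expect_true(all(diff(pic50_from_ic50(x)) < 0))
})

test_that("censored IC50 strings parse into value/flag pairs", {
  p <- parse_ic50(c("0.3", ">20", "> 5", "1"))
  expect_equal(p$ic50, c(0.3, 20, 5, 1))
  expect_equal(p$ic50_censored, c(FALSE, TRUE, TRUE, FALSE))
  expect_error(parse_ic50("n/a"), "unparseable")
  # a greater-than IC50 becomes a less-than pIC50 bound
  expect_equal(pic50_from_ic50(p$ic50[2]), 5 - log10(20), tolerance = 1e-12)
})

test_that("discriminant bands partition the line", {
  expect_equal(classify_df(c(-2.443, 0, 0.024, 0.5, 1, 3.743)),
               c("I", "I", "NC", "NC", "A", "A"))
  x <- stats::rnorm(200, 0, 3)
  cls <- classify_df(x)
  expect_true(all(cls %in% c("A", "I", "NC")))
  expect_equal(cls == "I", x <= 0)
  expect_equal(cls == "A", x >= 1)
})

test_that("the screening rule demands the window and the potency", {
  out <- screen(c(2.0, 3.931, 6.0, 1.0, 4.999), c(9.5, 8.612, 9.5, 9.5, 9.01))
  expect_equal(out$candidate, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # every candidate is also classified active
  expect_true(all(out$pred_class[out$candidate] == "A"))
})

test_that("expectancies follow their defining ratios", {
  e <- expectancy(1, 0)
  expect_equal(c(e$Ea, e$Ei), c(1, 0))
  e <- expectancy(0.5, 0.25)
  expect_equal(e$Ea, 0.4)
  expect_equal(e$Ei, 0.25 / 1.5, tolerance = 1e-12)
  e <- expectancy(0, 0)
  expect_equal(c(e$Ea, e$Ei), c(0, 0))
  expect_error(expectancy(1.2, 0), ">= 0")
})

test_that("the distribution diagram bins the study scores correctly", {
  ref <- table1_reference()
  cls <- load_table1()$class_exp
  pdd <- build_pdd(tibble::tibble(df = ref$df, class_exp = cls),
                   bin_width = 1)
  # [3, 4) holds exactly the two top-scoring actives and no inactive
  bin <- pdd[pdd$bin_lo == 3, ]
  expect_equal(bin$n_active, 2L)
  expect_equal(bin$n_inactive, 0L)
  expect_equal(bin$a, 2 / 6)
  expect_equal(bin$Ea, (2 / 6) / 1, tolerance = 1e-12)
  expect_equal(bin$Ei, 0)
  # normalization over bins
  expect_equal(sum(pdd$a), 1)
  expect_equal(sum(pdd$i), 1)
})

test_that("distribution diagrams satisfy their invariants on random data", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    d <- tibble::tibble(df = stats::rnorm(n, 0, 2),
                        class_exp = sample(c("A", "I"), n, replace = TRUE,
                                           prob = c(0.3, 0.7)))
    if (!any(d$class_exp == "A") || !any(d$class_exp == "I")) next
    pdd <- build_pdd(d, bin_width = 0.75)
    expect_equal(sum(pdd$a), 1)
    expect_equal(sum(pdd$i), 1)
    expect_true(all(pdd$Ea >= 0 & pdd$Ea <= 1))
    expect_true(all(pdd$Ei >= 0 & pdd$Ei <= 1))
    pure <- pdd$n_active > 0 & pdd$n_inactive == 0
    expect_equal(pdd$Ei[pure], rep(0, sum(pure)))
    expect_equal(pdd$Ea[pure], pdd$a[pure])
    # every compound lands in exactly one bin
    expect_equal(sum(pdd$n_active) + sum(pdd$n_inactive), n)
  }
  expect_error(build_pdd(tibble::tibble(df = 1, class_exp = "A")),
               "at least one")
})

test_that("all compounds in one bin give the degenerate expectancies", {
  d <- tibble::tibble(df = c(0.1, 0.2, 0.3),
                      class_exp = c("A", "I", "I"))
  pdd <- build_pdd(d, bin_width = 10)
  full <- pdd[pdd$n_active + pdd$n_inactive > 0, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$Ea, 1 / 2)  # a = i = 1
  expect_equal(full$Ei, 1 / 2)
})

test_that("the diagram has a plot method", {
  d <- tibble::tibble(df = c(-1, 0.5, 2, 3), class_exp = c("I", "I", "A", "A"))
  p <- ggplot2::autoplot(build_pdd(d))
  expect_s3_class(p, "ggplot")
})
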