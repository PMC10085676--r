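make_table <- function(f, od, blanks_f = c(90, 110), blanks_od = c(0.04, 0.06)) {
  dplyr::bind_rows(
    tibble::tibble(
      construct_id = "c", ligand_conc = 0, experimental_rep = 1L,
      biological_rep = seq_along(f), fluorescence_raw = f, od600_raw = od,
      is_blank = FALSE
    ),
    tibble::tibble(
      construct_id = "", ligand_conc = NA_real_, experimental_rep = 1L,
      biological_rep = NA_integer_, fluorescence_raw = blanks_f,
      od600_raw = blanks_od, is_blank = TRUE
    )
  )
}

test_that("normalization divides blank-corrected F by blank-corrected OD", {
  out <- normalize_measurements(make_table(1100, 0.45))
  expect_equal(out$value, (1100 - 100) / (0.45 - 0.05))  # = 2500
  # blanks-only table normalizes to an empty output
  blanks <- make_table(numeric(0), numeric(0))
  expect_identical(nrow(normalize_measurements(blanks)), 0L)
  expect_error(
    normalize_measurements(make_table(1100, 0.45)[1, ]),
    "blank"
  )
  expect_warning(
    out2 <- normalize_measurements(make_table(c(1100, 900), c(0.45, 0.02))),
    "OD600"
  )
  expect_identical(nrow(out2), 1L)
})

test_that("fold change is the ratio of group means", {
  expect_equal(fold_change(c(2, 4), c(2, 4)), 1.0)
  expect_equal(fold_change(c(3300, 3500), c(90, 110)), 34.0)
  expect_error(fold_change(numeric(0), 1), "nonempty")
  expect_error(fold_change(c(1, -3), c(1, 1)), "positive")
})

test_that("Welch test matches the textbook formulas", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  res <- welch_test(a, b)
  oracle <- welch_oracle(a, b)
  expect_equal(res$t, oracle$t)   # = -1
  expect_equal(res$df, oracle$df) # = 8
  expect_equal(res$p, oracle$p)
  expect_equal(res$t, -1)
  expect_equal(res$df, 8)

  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(sample(3:9, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:9, 1), mean = runif(1, -1, 1))
    res <- welch_test(x, y)
    oracle <- welch_oracle(x, y)
    expect_equal(res$t, oracle$t)
    expect_equal(res$df, oracle$df)
    expect_equal(res$p, oracle$p)
    swapped <- welch_test(y, x)
    expect_equal(swapped$t, -res$t)
    expect_equal(swapped$p, res$p)
  }
})

test_that("identical groups give t = 0, p = 1, tier ns", {
  res <- welch_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_identical(res$tier, "ns")
})

test_that("significance tiers use pre-correction thresholds; p_adj is capped", {
  res <- welch_test(c(1, 2, 3), c(1.1, 2.1, 3.1), m = 10)
  expect_equal(res$p_adj, min(1, res$p * 10))
  tbl <- tibble::tibble(p = c(0.02, 0.2, 1e-5))
  adj <- bonferroni(tbl, m = 10)
  expect_equal(adj$p_adj, c(0.2, 1, 1e-4))
  expect_identical(
    riboswitchEP:::significance_tier(c(0.2, 0.04, 0.009, 9e-4, 9e-5)),
    c("ns", "*", "**", "***", "****")
  )
})

test_that("dose-response fit recovers exact model parameters", {
  conc <- c(0, 0.001, 0.0025, 0.005, 0.01, 0.025, 0.1, 1)
  value <- 100 + 900 * conc / (0.01 + conc)
  fit <- fit_dose_response(conc, value)
  co <- fit$coefficients
  expect_equal(co[["a"]], 100, tolerance = 1e-6)
  expect_equal(co[["b"]], 900, tolerance = 1e-6)
  expect_equal(co[["ec50"]], 0.01, tolerance = 1e-6)
  # fitted curve at Z = EC50 sits halfway up the amplitude
  expect_equal(predict(fit, co[["ec50"]]) - co[["a"]], co[["b"]] / 2,
               tolerance = 1e-6)
  # fitted curve at Z = 0 equals the baseline a
  expect_equal(predict(fit, 0), co[["a"]])
})

test_that("dose-response fit is scale-equivariant", {
  set.seed(21)
  conc <- rep(c(0, 0.003, 0.01, 0.03, 0.3), each = 3)
  value <- (150 + 700 * conc / (0.02 + conc)) * (1 + rnorm(length(conc), 0, 0.05))
  f1 <- fit_dose_response(conc, value)
  f2 <- fit_dose_response(conc, value * 10)
  expect_equal(f2$coefficients[["a"]], 10 * f1$coefficients[["a"]], tolerance = 1e-6)
  expect_equal(f2$coefficients[["b"]], 10 * f1$coefficients[["b"]], tolerance = 1e-6)
  expect_equal(f2$coefficients[["ec50"]], f1$coefficients[["ec50"]], tolerance = 1e-6)
})

test_that("dose-response fit validates its inputs", {
  expect_error(fit_dose_response(c(0, 1), c(1, 2)), "3 distinct")
  expect_error(fit_dose_response(c(0.1, 0.2, 0.4), c(1, 2, 3)), "including 0")
})

test_that("noisy dose-response recovers EC50 within 15 percent", {
  set.seed(33)
  conc <- rep(c(0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.5, 1), each = 9)
  truth_ec50 <- 0.02
  value <- (100 + 900 * conc / (truth_ec50 + conc)) *
    (1 + rnorm(length(conc), 0, 0.05))
  fit <- fit_dose_response(conc, value)
  expect_lt(abs(fit$coefficients[["ec50"]] - truth_ec50) / truth_ec50, 0.15)
})

test_that("ON-state shift is a difference of group means", {
  expect_equal(delta_f_on(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(delta_f_on(c(1400, 1600), c(900, 1100)), 500)
  expect_equal(delta_f_on(c(500), c(1000)), -500)
  expect_error(delta_f_on(numeric(0), 1), "nonempty")
})

test_that("barrier model fit has the exact closed form", {
  r <- 1:6
  fit <- fit_barrier_model(r, 400 / r^2)
  expect_equal(fit$B, 400)
  expect_equal(fit$rss, 0)
  expect_equal(fit_barrier_model(1, 250)$B, 250)
  expect_true(is.na(fit_barrier_model(1, 250)$se))
  expect_error(fit_barrier_model(numeric(0), numeric(0)), "1 point")
  expect_error(fit_barrier_model(c(0.5, 1), c(1, 1)), "r >= 1")
  neg <- fit_barrier_model(1:3, c(-90, -20, -10), mutation_class = "WOBBLE")
  expect_true(neg$negative_B)
})

test_that("closed-form barrier fit agrees with a numerical least-squares solve", {
  set.seed(55)
  for (i in 1:10) {
    r <- sample(1:8, sample(3:8, 1), replace = TRUE)
    df <- 600 / r^2 + rnorm(length(r), 0, 40)
    closed <- fit_barrier_model(r, df)$B
    qr_solve <- unname(coef(lm(df ~ 0 + I(1 / r^2))))
    expect_equal(closed, qr_solve, tolerance = 1e-9)
  }
})

test_that("fraction readthrough is AT over total, within [0, 1]", {
  tbl <- tibble::tibble(lane = 1:3, terminated = c(50, 70, 0),
                        antiterminated = c(50, 30, 80))
  fr <- fraction_readthrough(tbl)
  expect_equal(fr$fraction_readthrough, c(0.5, 0.30, 1.0))
  expect_equal(
    fraction_readthrough(
      tibble::tibble(lane = 1, terminated = 10, antiterminated = 0)
    )$fraction_readthrough, 0
  )
  set.seed(77)
  rand <- tibble::tibble(lane = 1:50, terminated = runif(50, 0, 100),
                         antiterminated = runif(50, 0, 100))
  fr <- fraction_readthrough(rand)$fraction_readthrough
  expect_true(all(fr >= 0 & fr <= 1))
  expect_error(
    fraction_readthrough(tibble::tibble(lane = 1, terminated = 0,
                                        antiterminated = 0)),
    "zero"
  )
  expect_error(
    fraction_readthrough(tibble::tibble(lane = 1, terminated = -1,
                                        antiterminated = 2)),
    ">= 0"
  )
})
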