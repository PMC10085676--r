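#' Normalize well-level reporter measurements
#'
#' Implements the assay's normalization: the average blank fluorescence and
#' blank OD600 are subtracted from every sample well, and blank-corrected
#' fluorescence is divided by blank-corrected OD600 to normalize to cell
#' density. Blank rows are excluded from the output; sample rows whose
#' corrected OD is not positive are flagged invalid and dropped with a
#' warning.
#'
#' @param table a measurement table: one row per well with columns
#'   `construct_id`, `ligand_conc` (mM), `experimental_rep`,
#'   `biological_rep`, `fluorescence_raw`, `od600_raw`, `is_blank`.
#' @return a tibble of normalized measurements (`construct_id`,
#'   `ligand_conc`, `experimental_rep`, `biological_rep`, `value`).
#' @export
normalize_measurements <- function(table) {
  table <- tibble::as_tibble(table)
  req <- c("construct_id", "ligand_conc", "experimental_rep",
           "biological_rep", "fluorescence_raw", "od600_raw", "is_blank")
  missing <- setdiff(req, names(table))
  if (length(missing)) {
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  blanks <- table[table$is_blank, , drop = FALSE]
  if (nrow(blanks) == 0L) {
    stop("no blank wells: blank correction requires at least one blank row",
         call. = FALSE)
  }
  blank_f <- mean(blanks$fluorescence_raw)
  blank_od <- mean(blanks$od600_raw)
  samples <- table[!table$is_blank, , drop = FALSE]
  corrected_od <- samples$od600_raw - blank_od
  bad <- corrected_od <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) with corrected OD600 <= 0 excluded",
            call. = FALSE)
    samples <- samples[!bad, , drop = FALSE]
    corrected_od <- corrected_od[!bad]
  }
  tibble::tibble(
    construct_id = samples$construct_id,
    ligand_conc = samples$ligand_conc,
    experimental_rep = samples$experimental_rep,
    biological_rep = samples$biological_rep,
    value = (samples$fluorescence_raw - blank_f) / corrected_od
  )
}

#' Fold change between two measurement groups
#'
#' Dynamic range of a switch: the ratio of mean normalized fluorescence at
#' saturating ligand to the mean at zero ligand.
#'
#' @param values_high,values_low numeric vectors of normalized values.
#' @return `mean(values_high) / mean(values_low)`.
#' @export
fold_change <- function(values_high, values_low) {
  if (length(values_high) == 0L || length(values_low) == 0L) {
    stop("fold change requires nonempty groups", call. = FALSE)
  }
  mh <- mean(values_high); ml <- mean(values_low)
  if (mh <= 0 || ml <= 0) {
    stop("fold change requires positive group means", call. = FALSE)
  }
  mh / ml
}

significance_tier <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' Welch's t-test with the assay's significance reporting
#'
#' Two-tailed heteroscedastic (Welch) t-test with Welch-Satterthwaite
#' degrees of freedom. Significance tiers are assigned from the
#' pre-correction p-value at alpha = 0.05, 0.01, 0.001 and 0.0001, matching
#' how screens report them, while the Bonferroni-adjusted p-value
#' (`min(1, p * m)`) is carried alongside.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param m number of comparisons for the Bonferroni correction.
#' @return a one-row tibble: `t`, `df`, `p`, `p_adj`, `tier`.
#' @export
welch_test <- function(group_a, group_b, m = 1L) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("welch_test requires n >= 2 per group", call. = FALSE)
  }
  if (var(group_a) == 0 && var(group_b) == 0 &&
      mean(group_a) == mean(group_b)) {
    # degenerate identical constant groups: no evidence of difference
    res <- tibble::tibble(t = 0, df = length(group_a) + length(group_b) - 2, p = 1)
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE,
                        alternative = "two.sided")
    res <- tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                          p = ht$p.value)
  }
  res$p_adj <- pmin(1, res$p * m)
  res$tier <- significance_tier(res$p)
  res
}

#' Bonferroni-correct a set of test results
#'
#' @param results a tibble with a `p` column (e.g. rows from [welch_test()]).
#' @param m number of comparisons; defaults to `nrow(results)`.
#' @return `results` with `p_adj = min(1, p * m)` recomputed.
#' @export
bonferroni <- function(results, m = nrow(results)) {
  stopifnot("p" %in% names(results))
  results$p_adj <- pmin(1, results$p * m)
  results
}

#' Fit the sigmoidal dose-response model
#'
#' Least-squares fit of normalized fluorescence against ligand
#' concentration Z (mM) to `value = a + b * Z / (EC50 + Z)`, where `a`
#' scales the curve to the minimum response, `b` to the maximum, and EC50
#' is the half-maximal concentration. There is no Hill coefficient: the
#' model is the hyperbolic saturation curve. Initialization: `a0` = minimum
#' value, `b0` = max - min, `EC50_0` = geometric mean of the nonzero
#' concentrations; bounds `a >= 0`, `EC50 > 0`, `b` unconstrained in sign.
#'
#' @param conc ligand concentrations (mM), must include 0 and at least 3
#'   distinct values.
#' @param value normalized fluorescence values, same length.
#' @return a `dose_response_fit`: list with `coefficients` (named vector
#'   `a`, `b`, `ec50`), `se` (standard errors from the fit covariance),
#'   `rss`, `n`, and the `nls` object as `fit`.
#' @export
fit_dose_response <- function(conc, value) {
  stopifnot(length(conc) == length(value), is.numeric(conc), is.numeric(value))
  distinct <- sort(unique(conc))
  if (length(distinct) < 3L || !any(conc == 0)) {
    stop("dose-response fit needs >= 3 distinct concentrations including 0",
         call. = FALSE)
  }
  a0 <- min(value)
  b0 <- max(value) - min(value)
  ec0 <- exp(mean(log(distinct[distinct > 0])))
  dat <- data.frame(conc = conc, value = value)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ a + b * conc / (ec50 + conc),
      data = dat,
      start = list(a = a0, b = b0, ec50 = ec0),
      lower = c(a = 0, b = -Inf, ec50 = .Machine$double.eps),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("dose-response fit failed to converge: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  structure(
    list(
      coefficients = c(a = unname(est[["a"]]), b = unname(est[["b"]]),
                       ec50 = unname(est[["ec50"]])),
      se = c(a = unname(se[[1L]]), b = unname(se[[2L]]), ec50 = unname(se[[3L]])),
      rss = sum(stats::resid(fit)^2),
      n = length(value),
      fit = fit
    ),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("<dose_response_fit> a = %.4g, b = %.4g, EC50 = %.4g mM (n = %d)\n",
              co[["a"]], co[["b"]], co[["ec50"]], x$n))
  invisible(x)
}

#' Predict from a dose-response fit
#'
#' @param object a `dose_response_fit`.
#' @param conc concentrations (mM).
#' @param ... unused.
#' @return fitted normalized-fluorescence values.
#' @export
predict.dose_response_fit <- function(object, conc, ...) {
  co <- object$coefficients
  co[["a"]] + co[["b"]] * conc / (co[["ec50"]] + conc)
}

#' ON-state shift of a barrier mutant
#'
#' The increase in ON-state fluorescence of a mutant over the perfectly
#' complementary reference at saturating ligand: difference of group means
#' (negative values are allowed; wobble-direction-reversed mutants sit
#' below the reference).
#'
#' @param mutant_values,reference_values normalized values at the ON
#'   condition (1 mM ligand) for the mutant and the reference.
#' @return `mean(mutant_values) - mean(reference_values)`.
#' @export
delta_f_on <- function(mutant_values, reference_values) {
  if (length(mutant_values) == 0L || length(reference_values) == 0L) {
    stop("delta_f_on requires nonempty groups", call. = FALSE)
  }
  mean(mutant_values) - mean(reference_values)
}

#' Fit the inverse-square kinetic-barrier model
#'
#' Least-squares fit of ON-state shifts against barrier position to
#' \eqn{\Delta F_{ON}(r) = B / r^2}, where r is the barrier's distance in
#' nucleotides from the strand-displacement nucleation site and B is the
#' barrier-size parameter. The single-parameter least-squares optimum has
#' the closed form \eqn{\hat B = \sum_i \Delta F_i r_i^{-2} / \sum_i r_i^{-4}};
#' SE(B) comes from the residual variance. B may come out negative (and is
#' flagged) for wobble-class scans whose mutants sit below the reference.
#'
#' @param r barrier indices (positive integers).
#' @param delta_f ON-state shifts, same length.
#' @param mutation_class optional label (`"BULGE1"`, `"MISMATCH"`, ...).
#' @return a `barrier_fit`: list with `B`, `se`, `rss`, `points` (tibble of
#'   `r`, `delta_f`, `fitted`), `mutation_class`, `negative_B`.
#' @export
fit_barrier_model <- function(r, delta_f, mutation_class = NULL) {
  stopifnot(length(r) == length(delta_f))
  if (length(r) == 0L) stop("fit_barrier_model requires >= 1 point", call. = FALSE)
  r <- as.numeric(r)
  if (any(r < 1)) stop("barrier indices must satisfy r >= 1", call. = FALSE)
  w <- r^-2
  B <- sum(delta_f * w) / sum(w^2)
  fitted <- B * w
  rss <- sum((delta_f - fitted)^2)
  se <- if (length(r) > 1L) sqrt(rss / (length(r) - 1L) / sum(w^2)) else NA_real_
  structure(
    list(
      B = B, se = se, rss = rss,
      points = tibble::tibble(r = r, delta_f = delta_f, fitted = fitted),
      mutation_class = mutation_class,
      negative_B = B < 0
    ),
    class = "barrier_fit"
  )
}

#' @export
print.barrier_fit <- function(x, ...) {
  cat(sprintf("<barrier_fit>%s B = %.4g (SE %.3g, %d points)%s\n",
              if (is.null(x$mutation_class)) "" else paste0(" ", x$mutation_class, ":"),
              x$B, x$se, nrow(x$points),
              if (x$negative_B) " [negative B]" else ""))
  invisible(x)
}

#' Fraction readthrough from gel band intensities
#'
#' For single-round in vitro transcription, the fraction of transcripts
#' reading through the terminator: antiterminated band intensity over the
#' sum of terminated and antiterminated intensities, per lane.
#'
#' @param table a data frame with columns `lane`, `terminated`,
#'   `antiterminated` (intensities >= 0, not both zero in a lane).
#' @return a tibble with `lane` and `fraction_readthrough` in `[0, 1]`.
#' @export
fraction_readthrough <- function(table) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("lane", "terminated", "antiterminated") %in% names(table)))
  t <- table$terminated; at <- table$antiterminated
  if (any(t < 0 | at < 0)) stop("band intensities must be >= 0", call. = FALSE)
  if (any(t + at == 0)) {
    stop("lane with both band intensities zero", call. = FALSE)
  }
  tibble::tibble(lane = table$lane, fraction_readthrough = at / (at + t))
}
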