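#' Ground truth for the synthetic reporter assay
#'
#' Parameters of the generative model behind [simulate_assay()]. The true
#' normalized fluorescence of a construct at ligand concentration Z (mM) is
#' `(a + leak_shift) + (b + B / r^2) * Z / (EC50 + Z)`; the reference
#' (perfectly complementary) construct has no barrier term. Noise
#' composition: each experimental replicate (a "plate", with its own media
#' preparation) draws one multiplicative batch factor ~ LogNormal(0,
#' `batch_sd`), shared by every well on the plate; each biological
#' replicate draws an additional multiplicative Gaussian error with
#' coefficient of variation `cv`. Raw fluorescence is the true value times
#' the culture OD plus a blank (media autofluorescence) draw; raw OD is
#' culture OD plus a blank OD draw. The default replicate design is 3
#' experimental x 3 biological = 9 wells per condition.
#'
#' @param a baseline (leak) normalized fluorescence, > 0.
#' @param b reference response amplitude.
#' @param ec50 half-maximal ligand concentration in mM.
#' @param cv biological-replicate coefficient of variation.
#' @param batch_sd SD of the log batch factor per experimental replicate.
#' @param blank_f_mean,blank_f_sd blank fluorescence distribution (au).
#' @param blank_od_mean,blank_od_sd blank OD600 distribution.
#' @param od_true culture OD600 of the exponential-phase subculture.
#' @param n_experimental,n_biological replicate design.
#' @param n_blank blank wells per experimental replicate.
#' @return a list of class `ground_truth`.
#' @export
ground_truth <- function(a = 100, b = 900, ec50 = 0.05,
                         cv = 0.05, batch_sd = 0.05,
                         blank_f_mean = 100, blank_f_sd = 5,
                         blank_od_mean = 0.05, blank_od_sd = 0.005,
                         od_true = 0.4,
                         n_experimental = 3L, n_biological = 3L,
                         n_blank = 3L) {
  stopifnot(a > 0, ec50 > 0, cv >= 0, batch_sd >= 0,
            n_experimental >= 1L, n_biological >= 1L, n_blank >= 1L,
            od_true > 0)
  structure(
    list(a = a, b = b, ec50 = ec50, cv = cv, batch_sd = batch_sd,
         blank_f_mean = blank_f_mean, blank_f_sd = blank_f_sd,
         blank_od_mean = blank_od_mean, blank_od_sd = blank_od_sd,
         od_true = od_true,
         n_experimental = as.integer(n_experimental),
         n_biological = as.integer(n_biological),
         n_blank = as.integer(n_blank)),
    class = "ground_truth"
  )
}

#' True normalized fluorescence under a ground truth
#'
#' @param truth a `ground_truth`.
#' @param conc ligand concentration (mM).
#' @param leak_shift additive baseline change of the construct.
#' @param B,r barrier parameters (`B = 0` for the reference).
#' @return the noise-free normalized value.
#' @export
true_value <- function(truth, conc, leak_shift = 0, B = 0, r = 1) {
  (truth$a + leak_shift) +
    (truth$b + B / r^2) * conc / (truth$ec50 + conc)
}

#' Simulate a well-level reporter-assay measurement table
#'
#' Generates raw fluorescence/OD600 wells for a set of constructs across
#' ligand concentrations under a known [ground_truth()], with the replicate
#' structure and blank wells of the bulk assay, fully reproducible from
#' `seed`. Feeding the output through [normalize_measurements()] recovers
#' the true values exactly when all noise parameters are zero.
#'
#' @param truth a `ground_truth`.
#' @param constructs a data frame with columns `construct_id`,
#'   `leak_shift`, `B`, `r` (use `B = 0` for the reference; `r` is ignored
#'   when `B = 0`).
#' @param concentrations ligand concentrations in mM; must include 0.
#' @param seed integer seed; the RNG state is restored on exit.
#' @return a measurement-table tibble (columns `construct_id`,
#'   `ligand_conc`, `experimental_rep`, `biological_rep`,
#'   `fluorescence_raw`, `od600_raw`, `is_blank`); blank rows have
#'   `construct_id = ""` and `NA` replicate/concentration fields.
#' @export
simulate_assay <- function(truth, constructs, concentrations, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  constructs <- tibble::as_tibble(constructs)
  req <- c("construct_id", "leak_shift", "B", "r")
  missing <- setdiff(req, names(constructs))
  if (length(missing)) {
    stop("constructs table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!any(concentrations == 0)) {
    stop("concentrations must include 0 (the leak condition)", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(as.integer(seed))

  rows <- list()
  for (e in seq_len(truth$n_experimental)) {
    batch <- exp(rnorm(1L, 0, truth$batch_sd))
    for (ci in seq_len(nrow(constructs))) {
      cc <- constructs[ci, ]
      for (z in concentrations) {
        v0 <- true_value(truth, z, cc$leak_shift, cc$B, cc$r)
        for (bio in seq_len(truth$n_biological)) {
          v <- v0 * batch * (1 + rnorm(1L, 0, truth$cv))
          rows[[length(rows) + 1L]] <- tibble::tibble(
            construct_id = cc$construct_id,
            ligand_conc = z,
            experimental_rep = e,
            biological_rep = bio,
            fluorescence_raw = v * truth$od_true +
              rnorm(1L, truth$blank_f_mean, truth$blank_f_sd),
            od600_raw = truth$od_true +
              rnorm(1L, truth$blank_od_mean, truth$blank_od_sd),
            is_blank = FALSE
          )
        }
      }
    }
    for (k in seq_len(truth$n_blank)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        construct_id = "",
        ligand_conc = NA_real_,
        experimental_rep = e,
        biological_rep = NA_integer_,
        fluorescence_raw = rnorm(1L, truth$blank_f_mean, truth$blank_f_sd),
        od600_raw = rnorm(1L, truth$blank_od_mean, truth$blank_od_sd),
        is_blank = TRUE
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Paired dataset/truth suites for parameter-recovery tests
#'
#' For every combination of barrier size B and position r in the grid,
#' simulates one assay containing the perfectly complementary reference and
#' one barrier mutant, paired with its generating truth. Used to check that
#' the analysis pipeline ([normalize_measurements()] -> [delta_f_on()] ->
#' [fit_barrier_model()]) recovers known barrier sizes.
#'
#' @param B_values barrier sizes to simulate.
#' @param r_values barrier positions.
#' @param truth a `ground_truth`.
#' @param concentrations ligand concentrations (mM), including 0.
#' @param seed integer; each grid point gets a distinct sub-seed.
#' @return a list with one element per (B, r) pair: `list(table, B, r,
#'   truth, seed)`.
#' @export
make_recovery_suite <- function(B_values, r_values, truth = ground_truth(),
                                concentrations = c(0, 1), seed = 1L) {
  grid <- expand.grid(B = B_values, r = r_values)
  lapply(seq_len(nrow(grid)), function(i) {
    constructs <- tibble::tibble(
      construct_id = c("reference", "mutant"),
      leak_shift = c(0, 0),
      B = c(0, grid$B[i]),
      r = c(1, grid$r[i])
    )
    sub_seed <- as.integer(seed) + i - 1L
    list(
      table = simulate_assay(truth, constructs, concentrations, seed = sub_seed),
      B = grid$B[i], r = grid$r[i], truth = truth, seed = sub_seed
    )
  })
}
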