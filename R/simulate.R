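#' Describe a two-arm synthetic blood-count experiment
#'
#' The generator emulates the design of the motivating minipig studies: a
#' reference (electron-like) arm with six dose groups of three animals pooled
#' from two experiments, and a test (proton-like) arm with three dose groups
#' of three animals, each followed over a small set of time-points. Responses
#' follow the same model the analysis assumes -- fraction of control
#' \eqn{e^{-aD - bD^2}} with multiplicative lognormal inter-animal noise --
#' so parameter and RBE recovery can be quantified against known truth.
#'
#' Strata are rows of (cell_type, timepoint, arm, a, b). The convenience
#' builder [two_arm_strata()] links the arms through a true RBE:
#' `a_test = rbe * a_reference` and `b_test = rbe^2 * b_reference`, the unique
#' choice that makes the isoeffect dose ratio independent of dose.
#'
#' @param seed Integer seed; the dataset is bit-for-bit reproducible from it.
#' @param reference,test Per-arm design: a list with `doses` (Gy, positive,
#'   distinct), `n_per_group` and `max_dose`.
#' @param strata A tibble with columns `cell_type`, `timepoint`, `arm`, `a`,
#'   `b` giving the true coefficients per stratum.
#' @param noise_sigma SD of the log fraction (>= 0). The default 0.2
#'   reproduces the magnitude of reported group SEs (roughly 5--20% of the
#'   mean at n = 3).
#' @param baseline_counts Per cell type arithmetic mean and CV of the absolute
#'   pre-irradiation count (units 10^3/uL except RBC, 10^6/uL).
#' @param pairing Test-to-reference time-point map.
#' @param sham Generate 0 Gy sham animals (pure noise around 1)? They are
#'   never used in fits, matching the analysis convention, but make the
#'   dataset shape realistic.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1,
    reference = list(doses = c(5, 7.5, 7.7, 10, 15, 20), n_per_group = 3,
                     max_dose = 20),
    test = list(doses = c(5, 7.7, 10), n_per_group = 3, max_dose = 10),
    strata = two_arm_strata(),
    noise_sigma = 0.2,
    baseline_counts = default_baseline_counts(),
    pairing = default_pairing_map(),
    sham = TRUE) {
  for (arm in list(reference, test)) {
    if (any(arm$doses <= 0) || anyDuplicated(arm$doses)) {
      abort("arm doses must be positive and distinct")
    }
    if (arm$n_per_group < 1) abort("n_per_group must be >= 1")
  }
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  strata <- tibble::as_tibble(strata)
  stopifnot(all(c("cell_type", "timepoint", "arm", "a", "b") %in% names(strata)))
  missing_bl <- setdiff(unique(strata$cell_type), baseline_counts$cell_type)
  if (length(missing_bl) > 0) {
    abort(paste0("no baseline_counts for cell type(s): ",
                 paste(missing_bl, collapse = ", ")))
  }
  structure(list(seed = as.integer(seed), reference = reference, test = test,
                 strata = strata, noise_sigma = noise_sigma,
                 baseline_counts = tibble::as_tibble(baseline_counts),
                 pairing = pairing, sham = sham),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @param cell_type,timepoint_test Stratum identity on the test side; the
#'   reference row sits at the paired time-point.
#' @param a_reference,b_reference True reference-arm coefficients. The default
#'   slope 0.058 Gy^-1 is the day-1 WBC electron slope, the canonical
#'   reference curve of the motivating study.
#' @param rbe True RBE linking the arms.
#' @export
two_arm_strata <- function(cell_type = "WBC", timepoint_test = "d4",
                           a_reference = 0.058, b_reference = 0,
                           rbe = 1, pairing = default_pairing_map()) {
  if (!timepoint_test %in% names(pairing)) {
    abort(paste0("no pairing for test timepoint '", timepoint_test, "'"))
  }
  tibble::tibble(
    cell_type = cell_type,
    timepoint = c(unname(pairing[timepoint_test]), timepoint_test),
    arm = c("reference", "test"),
    a = c(a_reference, rbe * a_reference),
    b = c(b_reference, rbe^2 * b_reference))
}

#' @rdname simulation_config
#' @export
default_baseline_counts <- function() {
  # typical juvenile minipig CBC scale (10^3/uL; RBC 10^6/uL, platelet 10^3/uL)
  tibble::tibble(
    cell_type = hem_cell_types,
    mean = c(12, 6, 4.5, 0.4, 0.2, 6.5, 350),
    cv = 0.15)
}

#' Generate a synthetic two-arm blood-count dataset
#'
#' For each animal, a pre-irradiation count is drawn lognormally around the
#' cell type's baseline mean (with the configured CV); each post-irradiation
#' fraction is \eqn{e^{-aD - bD^2} \cdot \epsilon} with
#' \eqn{\ln\epsilon \sim N(0, \sigma^2)}, and the absolute count is that
#' fraction times the animal's own baseline. With `noise_sigma = 0` every
#' fraction equals the model value exactly.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_dataset` with `records` (blood-count
#'   records, both arms, pre-irradiation included) and `truth` (the config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  arms <- list(reference = config$reference, test = config$test)
  parts <- list()
  for (arm_name in names(arms)) {
    design <- arms[[arm_name]]
    strata <- config$strata[config$strata$arm == arm_name, , drop = FALSE]
    if (nrow(strata) == 0) next
    doses <- c(if (config$sham) 0, design$doses)
    animals <- tidyr::expand_grid(dose_gy = doses,
                                  rep = seq_len(design$n_per_group))
    animals$animal_id <- sprintf("%s_%04.1fGy_%d", arm_name,
                                 animals$dose_gy, animals$rep)
    base <- tidyr::expand_grid(animals[c("animal_id", "dose_gy")],
                               cell_type = unique(strata$cell_type)) |>
      dplyr::left_join(config$baseline_counts, by = "cell_type")
    sdlog <- sqrt(log(1 + base$cv^2))
    base$baseline <- stats::rlnorm(nrow(base), log(base$mean) - sdlog^2 / 2,
                                   sdlog)
    pre <- tibble::tibble(
      experiment_id = paste0("sim_", arm_name), arm = arm_name,
      animal_id = base$animal_id, dose_gy = base$dose_gy, timepoint = "pre",
      cell_type = base$cell_type, count = base$baseline)
    post <- dplyr::inner_join(base, strata,
                              by = "cell_type", relationship = "many-to-many")
    mu <- exp(-post$a * post$dose_gy - post$b * post$dose_gy^2)
    eps <- exp(rnorm(nrow(post), 0, config$noise_sigma))
    parts[[length(parts) + 1]] <- pre
    parts[[length(parts) + 1]] <- tibble::tibble(
      experiment_id = paste0("sim_", arm_name), arm = arm_name,
      animal_id = post$animal_id, dose_gy = post$dose_gy,
      timepoint = post$timepoint, cell_type = post$cell_type,
      count = mu * eps * post$baseline)
  }
  records <- as_count_records(dplyr::bind_rows(parts))
  structure(list(records = records, truth = config),
            class = "synthetic_dataset")
}

#' Ground-truth RBE of a synthetic stratum
#'
#' Returns `a_test / a_reference` for the requested cell type and test
#' time-point, after checking that the quadratic coefficients satisfy
#' `b_test = rbe^2 * b_reference` (to 1e-12), the condition under which the
#' isoeffect dose ratio is the same at every dose. When they do not, the true
#' RBE is dose-dependent and [dose_resolved_rbe()] gives the per-dose ratio.
#'
#' @param config A [simulation_config()].
#' @param cell_type,timepoint_test Stratum identity (test side).
#' @return A single dimensionless RBE.
#' @export
true_rbe <- function(config, cell_type = config$strata$cell_type[1],
                     timepoint_test = NULL) {
  st <- locate_strata(config, cell_type, timepoint_test)
  k <- if (st$ref$a > 0) st$test$a / st$ref$a else {
    if (st$ref$b <= 0) abort("reference stratum has a = b = 0")
    sqrt(st$test$b / st$ref$b)
  }
  if (abs(st$test$b - k^2 * st$ref$b) > 1e-12 * max(1, k^2 * st$ref$b)) {
    abort(paste0("true RBE is dose-dependent for ", cell_type, "/",
                 st$test$timepoint,
                 " (b_test != rbe^2 * b_reference); see dose_resolved_rbe()"))
  }
  k
}

#' @rdname true_rbe
#' @param doses Test doses at which to resolve the ratio (default: the test
#'   arm's design doses).
#' @return For `dose_resolved_rbe()`: a tibble with `dose_test` and `rbe`,
#'   the isoeffective reference dose at each test dose divided by that dose.
#' @export
dose_resolved_rbe <- function(config, cell_type = config$strata$cell_type[1],
                              timepoint_test = NULL,
                              doses = config$test$doses) {
  st <- locate_strata(config, cell_type, timepoint_test)
  effect <- st$test$a * doses + st$test$b * doses^2
  iso <- if (st$ref$b <= 0) effect / st$ref$a else
    (-st$ref$a + sqrt(st$ref$a^2 + 4 * st$ref$b * effect)) / (2 * st$ref$b)
  tibble::tibble(dose_test = doses, rbe = iso / doses)
}

locate_strata <- function(config, cell_type, timepoint_test) {
  s <- config$strata
  test <- s[s$arm == "test" & s$cell_type == cell_type, , drop = FALSE]
  if (!is.null(timepoint_test)) test <- test[test$timepoint == timepoint_test, ]
  if (nrow(test) != 1) {
    abort(paste0("expected exactly one test stratum for ", cell_type,
                 ", found ", nrow(test)))
  }
  tp_ref <- unname(config$pairing[test$timepoint])
  ref <- s[s$arm == "reference" & s$cell_type == cell_type &
             s$timepoint == tp_ref, , drop = FALSE]
  if (nrow(ref) != 1) {
    abort(paste0("no reference stratum for ", cell_type, "/", tp_ref))
  }
  list(test = as.list(test), ref = as.list(ref))
}
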