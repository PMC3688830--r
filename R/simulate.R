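# Seeded generator of synthetic sPCNL cohorts with the statistical
# structure the validation pipeline assumes: per-site stone involvement
# with pelvis-conditional enrichment, a logistic dependence of the
# stone-free outcome on the score, independent covariates, a second-rater
# noise model, and per-group complication rates.  Randomness comes from
# R's default Mersenne-Twister stream under the mandatory seed.

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic cohort
#' generator.  Defaults are calibrated to the development cohort: pelvis
#' involvement 0.87 (the fraction of pelvic-stone renometry categories),
#' base calyceal-site involvement 0.12 enriched 2.5-fold when the pelvis
#' is involved (together matching the mean score of about 3.15),
#' covariate distributions matching the published demographics (age
#' 54.9 +/- 13.6 y, BMI 25.5 +/- 3.6, largest diameter lognormal with
#' mean 23.6 and SD 9.2 mm, stone attenuation 820.7 +/- 336.8 HU,
#' hydronephrosis 16.8/37.4/27.1/18.7%), a rater-B noise model that
#' misses involved sites more often than it adds uninvolved ones (so the
#' second rater scores systematically lower), and per-group complication
#' probabilities 18.7/28.6/34.2%.
#'
#' @param n_patients Cohort size (default 155, the development cohort).
#' @param site_model List: `pelvis` (involvement probability),
#'   `calyceal` (base per-site probability for the 8 calyceal sites),
#'   `enrichment` (multiplier applied to `calyceal` when the pelvis is
#'   involved; capped at probability 1).
#' @param outcome_model List: `intercept` and `slope` on the log-odds of
#'   stone-free given the score.  `NULL` (default) means "fit from the
#'   reconstructed development cohort", the calibration used by
#'   [default_sim_config()].
#' @param covariate_model List of distribution parameters; see defaults.
#' @param rater_model List: `miss` (per-site probability that rater B
#'   misses an involved site) and `add` (probability of marking an
#'   uninvolved site).
#' @param complication_model Named numeric: probability of any
#'   complication per score group.
#' @param seed Integer seed; mandatory.
#' @return Object of class `"sim_config"` (a validated list).
#' @seealso [default_sim_config()], [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 155L,
                       site_model = list(pelvis = 0.87, calyceal = 0.12,
                                         enrichment = 2.5),
                       outcome_model = NULL,
                       covariate_model = list(
                         age = c(mean = 54.9, sd = 13.6),
                         bmi = c(mean = 25.5, sd = 3.6),
                         diameter_mm = c(mean = 23.6, sd = 9.2),
                         hounsfield = c(mean = 820.7, sd = 336.8),
                         hydronephrosis = c(normal = 0.168, mild = 0.374,
                                            moderate = 0.271,
                                            severe = 0.187),
                         male = 0.652, right = 0.49),
                       rater_model = list(miss = 0.10, add = 0.01),
                       complication_model = c(low = 0.187, medium = 0.286,
                                              high = 0.342),
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an integer seed is mandatory", call. = FALSE)
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  chk_prob <- function(p, what) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
      stop(what, " must be probabilities in [0, 1]", call. = FALSE)
  }
  chk_prob(site_model$pelvis, "site_model$pelvis")
  chk_prob(site_model$calyceal, "site_model$calyceal")
  if (site_model$enrichment < 0)
    stop("enrichment must be non-negative", call. = FALSE)
  if (!is.null(outcome_model))
    stopifnot(is.numeric(outcome_model$intercept),
              is.numeric(outcome_model$slope))
  chk_prob(rater_model$miss, "rater_model$miss")
  chk_prob(rater_model$add, "rater_model$add")
  chk_prob(complication_model, "complication_model")
  stopifnot(setequal(names(complication_model), group_levels()))
  hp <- covariate_model$hydronephrosis
  chk_prob(hp, "hydronephrosis probabilities")
  if (abs(sum(hp) - 1) > 1e-6)
    stop("hydronephrosis probabilities must sum to 1", call. = FALSE)
  structure(list(n_patients = n_patients, site_model = site_model,
                 outcome_model = outcome_model,
                 covariate_model = covariate_model,
                 rater_model = rater_model,
                 complication_model = complication_model,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation configuration calibrated to the development cohort
#'
#' Site probabilities are the package defaults (chosen so that the
#' simulated score distribution's mean falls within 0.3 of 3.15 at large
#' n); the outcome model's intercept and slope are obtained by fitting
#' the univariate score logistic model to [reconstructed_cohort()], so a
#' default simulated cohort reproduces both the score distribution and
#' the score-outcome gradient of the original series.
#'
#' @param seed Integer seed (mandatory).
#' @param n_patients Cohort size, default 155.
#' @return A `"sim_config"`.
#' @examples
#' cfg <- default_sim_config(seed = 1)
#' cfg$outcome_model
#' @export
default_sim_config <- function(seed, n_patients = 155L) {
  co <- reconstructed_cohort()
  fit <- fit_logistic(data.frame(score = co$sresc_score), co$stone_free)
  sim_config(n_patients = n_patients,
             outcome_model = list(
               intercept = unname(fit$coefficients["(Intercept)"]),
               slope = unname(fit$coefficients["score"])),
             seed = seed)
}

#' Serialise / restore a simulation configuration as JSON
#'
#' @param config A `"sim_config"`.
#' @param path JSON file path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns the restored `"sim_config"`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  # named numeric vectors must become JSON objects, not bare arrays
  namedToList <- function(x) {
    if (is.list(x)) lapply(x, namedToList)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(namedToList(unclass(config)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(n_patients = x$n_patients,
             site_model = as.list(x$site_model),
             outcome_model = if (is.null(x$outcome_model)) NULL
                             else as.list(x$outcome_model),
             covariate_model = lapply(x$covariate_model, unlist),
             rater_model = as.list(x$rater_model),
             complication_model = unlist(x$complication_model),
             seed = x$seed)
}

# Draw n stone maps as an n x 9 0/1 matrix.  Empty draws are
# rejection-resampled so the per-site probabilities are preserved
# conditional on non-emptiness.
.draw_maps <- function(n, site_model) {
  p_cal_base <- rep(site_model$calyceal, 8L)
  p_cal_pelvis <- pmin(1, p_cal_base * site_model$enrichment)
  draw <- function(k) {
    pelvis <- stats::rbinom(k, 1L, site_model$pelvis)
    pc <- ifelse(rep(pelvis, each = 8L) == 1L, p_cal_pelvis, p_cal_base)
    cal <- matrix(stats::rbinom(8L * k, 1L, pc), nrow = k, byrow = TRUE)
    cbind(pelvis, cal)
  }
  maps <- draw(n)
  repeat {
    empty <- which(rowSums(maps) == 0L)
    if (!length(empty)) break
    maps[empty, ] <- draw(length(empty))
  }
  colnames(maps) <- as.character(1:9)
  maps
}

#' Simulate a synthetic sPCNL cohort
#'
#' Draws, under the configured seed: a non-empty stone map per patient
#' (pelvis Bernoulli, calyceal sites Bernoulli with pelvis-conditional
#' enrichment, empty maps rejection-resampled), the S-ReSC score and
#' group via the scoring rule, the stone-free outcome from the logistic
#' outcome model given the score, covariates independently of the score,
#' and a complication grade with per-group probability.  Identical
#' configurations (including seed) give identical cohorts.
#'
#' @param config A `"sim_config"`; if its `outcome_model` is `NULL` the
#'   development-cohort fit is used (as in [default_sim_config()]).
#' @return An `sresc_cohort` with provenance `"simulated"`, carrying a
#'   `sites` column so rater pairs can be simulated from it.
#' @examples
#' co <- simulate_cohort(default_sim_config(seed = 7, n_patients = 50))
#' table(co$sresc_group)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  om <- config$outcome_model
  if (is.null(om)) {
    co <- reconstructed_cohort()
    fit <- fit_logistic(data.frame(score = co$sresc_score), co$stone_free)
    om <- list(intercept = unname(fit$coefficients[1]),
               slope = unname(fit$coefficients[2]))
  }
  set.seed(config$seed)
  n <- config$n_patients
  maps <- .draw_maps(n, config$site_model)
  score <- as.integer(rowSums(maps))
  group <- score_group(score)
  p_sf <- stats::plogis(om$intercept + om$slope * score)
  stone_free <- stats::rbinom(n, 1L, p_sf)

  cm <- config$covariate_model
  rl <- function(m, s) {  # lognormal matching a target mean and SD
    s2 <- log(1 + (s / m)^2)
    stats::rlnorm(n, log(m) - s2 / 2, sqrt(s2))
  }
  hydro <- sample(names(cm$hydronephrosis), n, replace = TRUE,
                  prob = cm$hydronephrosis)
  p_comp <- unname(config$complication_model[group])
  has_comp <- stats::rbinom(n, 1L, p_comp) == 1L
  # grade mix among patients with a complication, from the development
  # series' grade distribution (13/29/7/4 of 53 graded events)
  grades <- ifelse(has_comp,
                   sample(c("I", "II", "IIIA", "IIIB"), n, replace = TRUE,
                          prob = c(13, 29, 7, 4) / 53),
                   "none")
  sites_str <- apply(maps, 1L, function(r)
    paste(which(r == 1L), collapse = ";"))

  d <- data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    sites = sites_str,
    sresc_score = score,
    sresc_group = group,
    stone_free = stone_free,
    age = stats::rnorm(n, cm$age["mean"], cm$age["sd"]),
    sex = ifelse(stats::runif(n) < cm$male, "M", "F"),
    bmi = stats::rnorm(n, cm$bmi["mean"], cm$bmi["sd"]),
    laterality = ifelse(stats::runif(n) < cm$right, "R", "L"),
    largest_diameter_mm = rl(cm$diameter_mm["mean"], cm$diameter_mm["sd"]),
    mean_hu = stats::rnorm(n, cm$hounsfield["mean"], cm$hounsfield["sd"]),
    hydronephrosis = hydro,
    clavien_grade = grades,
    stringsAsFactors = FALSE)
  sresc_cohort(d, provenance = "simulated")
}

#' Simulate a rater pair for agreement analysis
#'
#' Rater A scores each patient's true stone map.  Rater B scores a
#' perturbed map in which each involved site is missed with probability
#' `rater_model$miss` and each uninvolved site is added with probability
#' `rater_model$add`; with misses more likely than additions, rater B
#' scores systematically lower, and disagreement concentrates at high
#' scores because patients with more involved sites offer more sites to
#' miss.  A perturbed map that would become empty keeps one of the truly
#' involved sites (a rater confronted with an obvious stone never scores
#' zero).
#'
#' @param cohort An `sresc_cohort` whose rows carry a non-empty `sites`
#'   column (e.g. from [simulate_cohort()]).
#' @param rater_model List with `miss` and `add` probabilities.
#' @param seed Integer seed (mandatory).
#' @return List with integer vectors `rater_a` and `rater_b`.
#' @examples
#' co <- simulate_cohort(default_sim_config(seed = 3, n_patients = 40))
#' r <- simulate_rater_pair(co, seed = 4)
#' mean(r$rater_a) - mean(r$rater_b)
#' @export
simulate_rater_pair <- function(cohort,
                                rater_model = list(miss = 0.10, add = 0.01),
                                seed) {
  stopifnot(inherits(cohort, "sresc_cohort"))
  if (missing(seed) || !is.numeric(seed))
    stop("an integer seed is required", call. = FALSE)
  if (is.null(cohort$sites) || any(is.na(cohort$sites)) ||
      any(!nzchar(cohort$sites)))
    stop("cohort records must carry stone maps in the sites column",
         call. = FALSE)
  set.seed(as.integer(seed))
  rater_a <- integer(nrow(cohort))
  rater_b <- integer(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    truth <- validate_sites(cohort$sites[i])
    rater_a[i] <- length(truth)
    kept <- truth[stats::runif(length(truth)) >= rater_model$miss]
    others <- setdiff(1:9, truth)
    added <- others[stats::runif(length(others)) < rater_model$add]
    seen <- sort(c(kept, added))
    if (!length(seen)) seen <- truth[sample.int(length(truth), 1L)]
    rater_b[i] <- length(seen)
  }
  list(rater_a = rater_a, rater_b = rater_b)
}
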