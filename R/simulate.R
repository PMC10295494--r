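#' @keywords internal
latent_variables <- function() {
  c("age", "height", "body_mass", "dbp", "pulse_pressure",
    "ao_diastolic_diameter", "ao_strain", "eat_thickness", "eat_volume")
}

# Underlying (mu, sigma) of a lower-truncated normal whose post-truncation
# mean/sd equal the targets. Solved numerically; direct closed forms exist
# only for the forward map.
truncnorm_moment_params <- function(mean, sd, lower) {
  moments <- function(mu, sigma) {
    alpha <- (lower - mu) / sigma
    h <- stats::dnorm(alpha) / stats::pnorm(alpha, lower.tail = FALSE)
    m <- mu + sigma * h
    v <- sigma^2 * (1 + alpha * h - h^2)
    c(m, sqrt(max(v, 0)))
  }
  obj <- function(p) {
    mm <- moments(p[1], exp(p[2]))
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-8) {
    stop("cannot moment-match truncated normal: mean ", mean, ", sd ", sd,
         ", lower ", lower, call. = FALSE)
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = lower)
}

# Quantile of the lower-truncated normal via the probability-integral map.
qtrunc_normal <- function(u, mu, sigma, lower) {
  p_low <- stats::pnorm((lower - mu) / sigma)
  mu + sigma * stats::qnorm(p_low + u * (1 - p_low))
}

#' Repair a correlation matrix to the nearest positive semi-definite one
#'
#' Symmetrises, forces a unit diagonal, and projects to the nearest
#' correlation matrix with [Matrix::nearPD()]. The Frobenius distance of
#' the repair is recorded; a distance above `max_distance` is treated as a
#' calibration error.
#'
#' @param r Square matrix of latent correlations.
#' @param max_distance Largest tolerated Frobenius repair distance.
#' @return The repaired matrix with attribute `repair_distance`.
#' @export
repair_correlation <- function(r, max_distance = 0.2) {
  if (!is.matrix(r) || nrow(r) != ncol(r)) {
    stop("correlation must be a square matrix", call. = FALSE)
  }
  if (any(abs(r) > 1)) stop("correlation entries must lie in [-1, 1]",
                            call. = FALSE)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  fixed <- as.matrix(Matrix::nearPD(r, corr = TRUE)$mat)
  dist <- sqrt(sum((fixed - r)^2))
  if (dist > max_distance) {
    stop("correlation matrix not repairable: Frobenius distance ",
         signif(dist, 3), " exceeds ", max_distance, call. = FALSE)
  }
  attr(fixed, "repair_distance") <- dist
  fixed
}

#' Construct a cohort simulation specification
#'
#' A `cohort_spec` bundles the cohort size, a seed, per-variable truncated
#' normal marginals (target post-truncation mean/SD plus a physical lower
#' bound), the latent Gaussian-copula correlation matrix, and the male sex
#' fraction. Underlying truncated-normal parameters are solved at
#' construction so repeated generation is cheap.
#'
#' @param n Cohort size.
#' @param seed Integer seed; replicate k of a study uses `seed + k`.
#' @param marginals Data frame with columns `variable`, `mean`, `sd`,
#'   `lower` covering every latent variable.
#' @param correlation Latent correlation matrix (rows/cols in the order of
#'   `marginals$variable`); repaired to the nearest PSD correlation.
#' @param sex_fraction_male Proportion of male records.
#' @return An object of class `cohort_spec`.
#' @seealso [default_spec()], [generate_cohort()], [calibrate_spec()]
#' @export
cohort_spec <- function(n, seed, marginals, correlation,
                        sex_fraction_male = 0.495) {
  stopifnot(n >= 2, is.data.frame(marginals),
            all(c("variable", "mean", "sd", "lower") %in% names(marginals)))
  vars <- latent_variables()
  if (!setequal(marginals$variable, vars)) {
    stop("marginals must cover exactly: ", paste(vars, collapse = ", "),
         call. = FALSE)
  }
  if (any(marginals$sd <= 0)) stop("marginal SDs must be > 0", call. = FALSE)
  marginals <- marginals[match(vars, marginals$variable), ]
  pars <- lapply(seq_len(nrow(marginals)), function(i) {
    truncnorm_moment_params(marginals$mean[i], marginals$sd[i],
                            marginals$lower[i])
  })
  marginals$mu <- vapply(pars, `[[`, numeric(1), "mu")
  marginals$sigma <- vapply(pars, `[[`, numeric(1), "sigma")
  dimnames(correlation) <- list(vars, vars)
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 marginals = marginals,
                 correlation = repair_correlation(correlation),
                 sex_fraction_male = sex_fraction_male),
            class = "cohort_spec")
}

#' Default cohort specification
#'
#' Calibration values for a 97-patient CCTA cohort: age 63.48 +/- 8.50 y,
#' height 1.67 +/- 0.07 m, body mass 74.16 +/- 11.03 kg, SBP/DBP
#' 143.20 +/- 7.78 / 88.40 +/- 5.66 mmHg, aortic diastolic diameter
#' 33.42 +/- 4.36 mm, aortic strain 3.29 +/- 2.37 %, EAT thickness
#' 9.51 +/- 3.33 mm, EAT volume 60.03 +/- 21.07 mL, 49.5% men. Blood
#' pressure is parameterised as (DBP, pulse pressure) so that SBP > DBP
#' holds by construction; the pulse-pressure SD is derived from the SBP and
#' DBP SDs under latent independence. Strain is the latent elasticity
#' variable: the systolic diameter is derived as
#' diastolic * (1 + strain/100), guaranteeing systolic >= diastolic, and
#' strain is truncated below at 0.2% so the stiffness index stays finite.
#'
#' The latent correlation block places the negative strain-EAT association
#' that drives the positive EAT-stiffness correlations of the derived
#' indices; [calibrate_spec()] refines the two strain-EAT entries so the
#' induced derived-index correlations hit their targets.
#'
#' @param n Cohort size (default 97).
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
default_spec <- function(n = 97, seed = 1) {
  marginals <- data.frame(
    variable = latent_variables(),
    mean = c(63.48, 1.67, 74.16, 88.40, 54.80, 33.42, 3.29, 9.51, 60.03),
    sd   = c(8.50, 0.07, 11.03, 5.66, sqrt(7.78^2 - 5.66^2), 4.36, 2.37,
             3.33, 21.07),
    lower = c(30, 1.40, 40, 60, 20, 20, 0.2, 1, 5),
    stringsAsFactors = FALSE
  )
  vars <- latent_variables()
  r <- diag(length(vars))
  dimnames(r) <- list(vars, vars)
  set_r <- function(a, b, v) {
    r[a, b] <<- v
    r[b, a] <<- v
  }
  set_r("height", "body_mass", 0.45)
  set_r("age", "pulse_pressure", 0.25)
  set_r("age", "ao_strain", -0.25)
  set_r("age", "ao_diastolic_diameter", 0.20)
  set_r("height", "ao_diastolic_diameter", 0.20)
  set_r("body_mass", "eat_thickness", 0.35)
  set_r("body_mass", "eat_volume", 0.40)
  set_r("ao_strain", "pulse_pressure", -0.15)
  set_r("ao_strain", "eat_thickness", -0.35)
  set_r("ao_strain", "eat_volume", -0.55)
  set_r("eat_thickness", "eat_volume", 0.60)
  cohort_spec(n = n, seed = seed, marginals = marginals, correlation = r)
}

#' Generate a synthetic cohort
#'
#' Draws `spec$n` patient records from a Gaussian copula with the spec's
#' latent correlation matrix and moment-matched lower-truncated normal
#' marginals. SBP is assembled as DBP + pulse pressure and the systolic
#' aortic diameter as diastolic * (1 + strain/100), so every record
#' satisfies the physical invariants by construction. Generation is
#' deterministic for a fixed spec and seed.
#'
#' @param spec A `cohort_spec`.
#' @param seed Optional override of `spec$seed` (used for replicates).
#' @return A validated cohort data frame with the spec attached as
#'   attribute `"spec"`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  n <- spec$n
  vars <- latent_variables()
  sex <- ifelse(stats::runif(n) < spec$sex_fraction_male, "male", "female")
  z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*%
    chol(spec$correlation)
  u <- stats::pnorm(z)
  x <- vapply(seq_along(vars), function(j) {
    m <- spec$marginals[j, ]
    qtrunc_normal(u[, j], m$mu, m$sigma, m$lower)
  }, numeric(n))
  colnames(x) <- vars
  cohort <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    age = x[, "age"],
    sex = sex,
    height = x[, "height"],
    body_mass = x[, "body_mass"],
    sbp = x[, "dbp"] + x[, "pulse_pressure"],
    dbp = x[, "dbp"],
    ao_diastolic_diameter = x[, "ao_diastolic_diameter"],
    ao_systolic_diameter = x[, "ao_diastolic_diameter"] *
      (1 + x[, "ao_strain"] / 100),
    eat_thickness = x[, "eat_thickness"],
    eat_volume = x[, "eat_volume"],
    stringsAsFactors = FALSE
  )
  validate_cohort(cohort)
  attr(cohort, "spec") <- spec
  cohort
}

#' Generate replicate cohorts
#'
#' Replicate k uses seed `spec$seed + k`, giving independent but fully
#' reproducible streams.
#'
#' @param spec A `cohort_spec`.
#' @param reps Number of replicate cohorts.
#' @return A list of cohort data frames.
#' @export
generate_cohorts <- function(spec, reps) {
  lapply(seq_len(reps), function(k) generate_cohort(spec, seed = spec$seed + k))
}

#' Summarise a generated cohort against its specification
#'
#' Computes per-variable achieved means/SDs on the latent-observable scale
#' (pulse pressure and strain reconstructed from the record fields), the
#' achieved Pearson correlation matrix, a normal-scores correlation matrix
#' estimating the latent copula correlations, and -- when the spec is
#' available -- the achieved-minus-target mean bias per variable.
#'
#' @param cohort A cohort data frame (or rbind of several).
#' @param spec Optional `cohort_spec`; defaults to the attached one.
#' @return A list with `moments`, `pearson`, `latent`, and (if a spec is
#'   present) `mean_bias`.
#' @export
summarize_cohort <- function(cohort, spec = attr(cohort, "spec")) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  x <- cbind(
    age = cohort$age, height = cohort$height, body_mass = cohort$body_mass,
    dbp = cohort$dbp, pulse_pressure = cohort$sbp - cohort$dbp,
    ao_diastolic_diameter = cohort$ao_diastolic_diameter,
    ao_strain = 100 * (cohort$ao_systolic_diameter -
                         cohort$ao_diastolic_diameter) /
      cohort$ao_diastolic_diameter,
    eat_thickness = cohort$eat_thickness, eat_volume = cohort$eat_volume
  )
  moments <- data.frame(
    variable = colnames(x),
    mean = colMeans(x),
    sd = apply(x, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ns <- apply(x, 2, function(v) {
    stats::qnorm((rank(v) - 0.5) / length(v))
  })
  out <- list(moments = moments,
              pearson = stats::cor(x),
              latent = stats::cor(ns))
  if (!is.null(spec)) {
    tgt <- spec$marginals[match(moments$variable, spec$marginals$variable), ]
    out$mean_bias <- moments$mean - tgt$mean
    names(out$mean_bias) <- moments$variable
  }
  out
}

# Mean per-cohort Pearson correlation between the derived stiffness index
# and the two BSA-indexed EAT measures, over replicate cohorts.
induced_index_correlations <- function(spec, reps, seed_offset = 0) {
  rs <- vapply(seq_len(reps), function(k) {
    d <- derive_indices(generate_cohort(spec, seed = spec$seed + seed_offset + k))
    c(stats::cor(d$ao_stiffness_index, d$eat_volume_index),
      stats::cor(d$ao_stiffness_index, d$eat_thickness_index))
  }, numeric(2))
  c(volume_index = mean(rs[1, ]), thickness_index = mean(rs[2, ]))
}

#' Calibrate the latent strain-EAT correlations to derived-index targets
#'
#' The association targets are stated on the scale of *derived* indices
#' (stiffness index vs BSA-indexed EAT), while the copula operates on the
#' latent (strain, EAT) pairs. Because the strain-to-index transforms are
#' monotone but nonlinear, the induced correlations differ somewhat from
#' the latent ones. This fixed-point calibration iterates: measure the
#' induced mean per-cohort correlation by simulation, scale each latent
#' target by the target/induced ratio (capped at |0.95|), repair the
#' matrix to PSD, and stop when within `tol` or after `max_iter` rounds.
#'
#' @param spec A `cohort_spec` to calibrate.
#' @param targets Named vector of target correlations between the
#'   stiffness index and the EAT volume index / thickness index.
#' @param reps Replicate cohorts per measurement round. The default keeps
#'   the Monte-Carlo standard error of the measured correlation below
#'   `tol`, so the iteration does not chase noise.
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the induced correlations.
#' @return The calibrated `cohort_spec`, with a `calibration` attribute
#'   recording the iteration trace.
#' @export
calibrate_spec <- function(spec,
                           targets = c(volume_index = 0.55,
                                       thickness_index = 0.24),
                           reps = 80, max_iter = 5, tol = 0.015) {
  stopifnot(inherits(spec, "cohort_spec"))
  trace <- list()
  for (iter in seq_len(max_iter)) {
    induced <- induced_index_correlations(spec, reps,
                                          seed_offset = 100000 + iter * 1000)
    trace[[iter]] <- induced
    if (all(abs(induced - targets) < tol)) break
    r <- spec$correlation
    for (pair in list(c("eat_volume", "volume_index"),
                      c("eat_thickness", "thickness_index"))) {
      latent_var <- pair[1]
      tgt <- targets[[pair[2]]]
      got <- induced[[pair[2]]]
      if (got <= 0) next  # no signal to scale; leave the entry alone
      new_val <- max(-0.95, min(0.95,
                                r["ao_strain", latent_var] * tgt / got))
      r["ao_strain", latent_var] <- new_val
      r[latent_var, "ao_strain"] <- new_val
    }
    spec$correlation <- repair_correlation(r)
  }
  attr(spec, "calibration") <- trace
  spec
}
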