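# Synthetic dual-phase phantom cohorts with planted habitat structure.
# The generator emulates the study conditions the pipeline was designed
# for: co-registered arterial/venous tumor volumes whose joint voxel
# intensity distribution is a K-component mixture arranged as concentric
# shells around a low-attenuation necrosis-like core, per-patient habitat
# composition that differs between LNM classes, and exponential survival
# with class-dependent hazard.

# Run expr with a private RNG stream; global .Random.seed is restored.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

.derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919 + 1) %% 2147483629)
}

#' Phantom specification
#'
#' Defines the synthetic cohort conditions: planted habitat count and
#' per-habitat (arterial, venous) mean intensities, the intensity spread,
#' tumor size range, the composition shift between LNM classes, and
#' class-dependent survival. Defaults give five habitats whose adjacent
#' means are separated by about 64 HU (>= 4 x the 10 HU sd, so clustering
#' is identifiable), tumors of 12-18 mm radius on a 1 mm grid, a 0.12
#' volume-fraction shift planted in habitats 1 and 5, and exponential
#' survival with medians 17 (LNM-) and 9 (LNM+) months under roughly 30%
#' censoring.
#'
#' @param n_patients number of patients.
#' @param k_true planted habitat count (>= 2); habitat 1 is the
#'   low-intensity necrosis-like core, habitat `k_true` the outer shell.
#' @param habitat_means `k_true` x 2 matrix of (arterial, venous) HU means,
#'   rows ordered core to rim and by ascending venous mean.
#' @param intensity_sd within-habitat intensity sd (HU), both channels.
#' @param noise_sd additional acquisition noise sd (HU).
#' @param radius_range tumor equivalent-radius range in mm.
#' @param perturb_amp amplitude of the angular perturbation of shell
#'   boundaries (fraction of normalized radius).
#' @param base_fractions expected habitat volume fractions (sum 1).
#' @param composition_effect total volume fraction shifted toward
#'   `effect_habitats` in LNM+ patients.
#' @param effect_habitats habitats receiving the composition shift.
#' @param dirichlet_conc concentration of the per-patient Dirichlet draw
#'   around the class mean fractions.
#' @param median_surv length-2 vector, median survival (months) for
#'   LNM- and LNM+.
#' @param horizon administrative censoring horizon (months).
#' @param dropout_max upper bound of the uniform dropout time (months).
#' @param wbc_low_prob P(WBC below cutoff) per class (LNM-, LNM+).
#' @param seed master seed; all randomness derives from it.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 20L,
                         k_true = 5L,
                         habitat_means = cbind(
                           arterial = c(0, 45, 90, 135, 180),
                           venous   = c(10, 55, 100, 145, 190)),
                         intensity_sd = 10,
                         noise_sd = 0,
                         radius_range = c(12, 18),
                         perturb_amp = 0.08,
                         base_fractions = rep(1 / k_true, k_true),
                         composition_effect = 0.12,
                         effect_habitats = c(1L, k_true),
                         dirichlet_conc = 100,
                         median_surv = c(17, 9),
                         horizon = 54,
                         dropout_max = 60,
                         wbc_low_prob = c(17 / 51, 29 / 52),
                         seed = 0L) {
  k_true <- as.integer(k_true)
  if (k_true < 2L) stop("k_true must be >= 2")
  habitat_means <- as.matrix(habitat_means)
  if (nrow(habitat_means) != k_true || ncol(habitat_means) != 2L)
    stop("habitat_means must be k_true x 2 (arterial, venous)")
  sd_tot <- sqrt(intensity_sd^2 + noise_sd^2)
  d <- as.matrix(stats::dist(habitat_means))
  min_sep <- min(d[upper.tri(d)])
  if (sd_tot > 0 && min_sep < 4 * sd_tot)
    stop(sprintf("habitat means separated by %.1f HU < 4 x sd (%.1f HU); clustering not identifiable",
                 min_sep, 4 * sd_tot))
  if (abs(sum(base_fractions) - 1) > 1e-8 || any(base_fractions <= 0))
    stop("base_fractions must be positive and sum to 1")
  if (length(base_fractions) != k_true) stop("base_fractions length != k_true")
  fr_pos <- .class_fractions(base_fractions, composition_effect, effect_habitats)
  if (any(fr_pos <= 0))
    stop("composition_effect produces non-positive habitat fractions")
  structure(list(
    n_patients = as.integer(n_patients), k_true = k_true,
    habitat_means = habitat_means, intensity_sd = intensity_sd,
    noise_sd = noise_sd, radius_range = radius_range,
    perturb_amp = perturb_amp, base_fractions = base_fractions,
    composition_effect = composition_effect,
    effect_habitats = as.integer(effect_habitats),
    dirichlet_conc = dirichlet_conc, median_surv = median_surv,
    horizon = horizon, dropout_max = dropout_max,
    wbc_low_prob = wbc_low_prob, seed = as.integer(seed)),
    class = "phantom_spec")
}

# Mean fractions for a class: shift `effect` into the effect habitats,
# uniformly out of the others.
.class_fractions <- function(base, effect, effect_habitats) {
  k <- length(base)
  delta <- numeric(k)
  delta[effect_habitats] <- effect / length(effect_habitats)
  rest <- setdiff(seq_len(k), effect_habitats)
  delta[rest] <- -effect / length(rest)
  base + delta
}

#' Generate one synthetic dual-phase patient
#'
#' Builds an ellipsoidal tumor on a 1 mm isotropic grid, assigns each
#' in-mask voxel a true habitat by concentric shells (with angular
#' perturbation of the boundaries) whose expected volume fractions are
#' `fractions`, and draws the (arterial, venous) intensity pair of each
#' voxel from the habitat's bivariate normal. Deterministic given
#' (`spec$seed`, `patient_index`).
#'
#' @param spec a [phantom_spec()].
#' @param patient_index 1-based patient index (seeds the patient stream).
#' @param fractions habitat volume fractions for this patient (defaults to
#'   `spec$base_fractions`).
#' @return list with elements `arterial`, `venous` ([volume_image()]),
#'   `mask` ([roi_mask()]), and `truth` (true per-voxel habitat labels,
#'   fractions, radius).
#' @export
generate_patient <- function(spec, patient_index,
                             fractions = spec$base_fractions) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions <= 0))
    stop("fractions must be positive and sum to 1")
  .with_seed(.derive_seed(spec$seed, patient_index), {
    pid <- sprintf("P%03d", patient_index)
    r <- runif(1, spec$radius_range[1], spec$radius_range[2])
    semi <- r * runif(3, 0.85, 1.15)
    dims <- as.integer(2 * ceiling(semi) + 7)
    if (any(dims < 3L)) stop("grid too small for requested radius")
    ctr <- (dims + 1) / 2
    ax <- lapply(1:3, function(a) (seq_len(dims[a]) - ctr[a]) / semi[a])
    X <- array(ax[[1]], dims)
    Y <- array(rep(ax[[2]], each = dims[1]), dims)
    Z <- array(rep(ax[[3]], each = dims[1] * dims[2]), dims)
    rho <- sqrt(X^2 + Y^2 + Z^2)
    theta <- atan2(Y, X)
    phi <- acos(ifelse(rho > 0, Z / pmax(rho, 1e-12), 0))
    ph <- runif(2, 0, 2 * pi)
    rho_p <- rho * (1 + spec$perturb_amp * sin(3 * theta + ph[1]) *
                      cos(2 * phi + ph[2]))
    inmask <- rho_p <= 1
    if (!any(inmask)) stop("grid too small for requested radius")
    cutoffs <- cumsum(fractions)^(1 / 3)
    hab <- findInterval(rho_p[inmask], cutoffs[-length(cutoffs)],
                        left.open = TRUE) + 1L
    hab <- pmin(pmax(hab, 1L), spec$k_true)
    n_in <- sum(inmask)
    labels <- array(0L, dims)
    labels[inmask] <- hab
    sd_h <- spec$intensity_sd
    art <- array(rnorm(prod(dims), 70, 15), dims)   # liver-like background
    ven <- array(rnorm(prod(dims), 110, 15), dims)
    art[inmask] <- spec$habitat_means[hab, 1] +
      (if (sd_h > 0) rnorm(n_in, 0, sd_h) else 0)
    ven[inmask] <- spec$habitat_means[hab, 2] +
      (if (sd_h > 0) rnorm(n_in, 0, sd_h) else 0)
    if (spec$noise_sd > 0) {
      art <- art + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
      ven <- ven + array(rnorm(prod(dims), 0, spec$noise_sd), dims)
    }
    list(
      arterial = volume_image(art, c(1, 1, 1), c(0, 0, 0), "arterial", pid),
      venous = volume_image(ven, c(1, 1, 1), c(0, 0, 0), "venous", pid),
      mask = roi_mask(array(as.integer(inmask), dims), c(1, 1, 1),
                      c(0, 0, 0), pid),
      truth = list(labels = labels, fractions = fractions, radius = r,
                   patient_id = pid))
  })
}

#' Generate a synthetic cohort
#'
#' Near-balanced LNM classes (`floor(n/2)` negative, `ceiling(n/2)`
#' positive), per-patient habitat fractions drawn from a Dirichlet around
#' class-dependent means (LNM+ shifted by `composition_effect` toward the
#' effect habitats), exponential survival with class medians
#' `spec$median_surv` censored administratively plus by uniform dropout,
#' and a dichotomized WBC-like covariate with class-dependent prevalence.
#'
#' @param spec a [phantom_spec()].
#' @param n_patients overrides `spec$n_patients` if given.
#' @return list with `patients` (per-patient output of
#'   [generate_patient()]), `cohort` (a `cohort_table`), and `truth`.
#' @export
generate_cohort <- function(spec, n_patients = spec$n_patients) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- as.integer(n_patients)
  if (n < 4L) stop("need at least 4 patients")
  lnm <- c(rep(0L, floor(n / 2)), rep(1L, ceiling(n / 2)))
  fr_class <- rbind(.class_fractions(spec$base_fractions, 0, spec$effect_habitats),
                    .class_fractions(spec$base_fractions,
                                     spec$composition_effect,
                                     spec$effect_habitats))
  frac_mat <- matrix(NA_real_, n, spec$k_true)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    f <- .with_seed(.derive_seed(spec$seed, 500000L + i), {
      g <- rgamma(spec$k_true, shape = spec$dirichlet_conc * fr_class[lnm[i] + 1L, ])
      g / sum(g)
    })
    frac_mat[i, ] <- f
    patients[[i]] <- generate_patient(spec, i, fractions = f)
  }
  surv <- .with_seed(.derive_seed(spec$seed, 900001L), {
    rate <- log(2) / spec$median_surv[lnm + 1L]
    t_true <- rexp(n, rate)
    cens <- pmin(spec$horizon, runif(n, 0, spec$dropout_max))
    wbc <- rbinom(n, 1L, spec$wbc_low_prob[lnm + 1L])
    data.frame(t_true = t_true,
               survival_time = pmin(t_true, cens),
               event = as.integer(t_true <= cens),
               wbc = ifelse(wbc == 1L, "low", "high"))
  })
  cohort <- as_cohort_table(data.frame(
    patient_id = vapply(patients, function(p) p$truth$patient_id, ""),
    lnm_status = lnm,
    wbc = surv$wbc,
    survival_time = surv$survival_time,
    event = surv$event,
    dissected = 1L,
    stringsAsFactors = FALSE))
  truth <- list(lnm = lnm, fractions = frac_mat,
                true_time = surv$t_true,
                class_fractions = fr_class,
                habitat_means = spec$habitat_means)
  list(patients = patients, cohort = cohort, truth = truth)
}
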