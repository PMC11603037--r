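#' Configuration for the synthetic perioperative cohort generator
#'
#' The generator emulates the structure of a perioperative delirium cohort:
#' roughly 8.3% of surgeries POD positive, multiple surgeries for some
#' patients, irregular per-feature observation times with a modal spacing of
#' about 3 minutes, surgery lengths of a few hours, and Nu-DESC assessments in
#' the recovery room shortly after anesthesia end. Class signal is injected
#' through three controllable channels per dynamic feature: a mean shift
#' (`delta_mean`, feature units), a within-window slope
#' (`delta_slope_per_min`, feature units per minute, centred on the midpoint
#' of `effect_window` so the window mean is unchanged), and an
#' observation-rate shift (`delta_log_obs_rate`, log multiplier of the Poisson
#' observation rate; informative missingness). Patients carry per-feature
#' random intercepts shared exactly across their surgeries.
#'
#' Latent trajectories are stationary AR(1) processes on a 1-minute grid
#' around the (possibly shifted) feature mean, observed at Poisson event times
#' with i.i.d. Gaussian measurement noise.
#'
#' @param n_patients number of patients.
#' @param surgeries_per_patient_rate Poisson rate of extra surgeries per
#'   patient (every patient has at least one).
#' @param prevalence_target per-surgery POD probability.
#' @param surgery_length_meanlog,surgery_length_sdlog,surgery_length_range
#'   log-normal parameters (minutes) and clamping range for anesthesia
#'   duration.
#' @param feature_menu `data.frame` with columns `name, baseline_mean,
#'   baseline_sd, ar1_coef, noise_sd, obs_rate_per_min`.
#' @param effects `data.frame` with columns `feature, delta_mean,
#'   delta_slope_per_min, delta_log_obs_rate`, applied to POD-positive
#'   surgeries only.
#' @param effect_window two-minute vector `[from, to]` (relative to
#'   anesthesia begin) inside which the slope effect acts.
#' @param static_menu `data.frame` with columns `name, base_mean, base_sd,
#'   delta_mean` (shift for POD-positive surgeries).
#' @param patient_intercept_sd standard deviation of the per-patient,
#'   per-feature random intercept (feature units).
#' @param noise_het_sd log-scale standard deviation of a per-surgery
#'   multiplicative factor on the measurement noise (monitor- and
#'   patient-level variability in recording noisiness).
#' @param nudesc_extra_rate Poisson rate of assessments beyond the first.
#' @param nudesc_delay_mean,nudesc_delay_sd minutes between anesthesia end and
#'   an assessment.
#' @param seed default seed stored with the config.
#'
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       surgeries_per_patient_rate = 0.19,
                       prevalence_target = 0.083,
                       surgery_length_meanlog = log(170),
                       surgery_length_sdlog = 0.35,
                       surgery_length_range = c(45, 480),
                       feature_menu = default_feature_menu(),
                       effects = NULL,
                       effect_window = c(0, 30),
                       static_menu = default_static_menu(),
                       patient_intercept_sd = 0.5,
                       noise_het_sd = 0.3,
                       nudesc_extra_rate = 0.2,
                       nudesc_delay_mean = 37,
                       nudesc_delay_sd = 27,
                       seed = 1L) {
  if (is.null(effects)) {
    effects <- data.frame(
      feature = feature_menu$name,
      delta_mean = 0, delta_slope_per_min = 0, delta_log_obs_rate = 0,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(
    prevalence_target > 0, prevalence_target < 1,
    all(feature_menu$obs_rate_per_min > 0),
    all(feature_menu$ar1_coef >= 0), all(feature_menu$ar1_coef < 1),
    all(effects$feature %in% feature_menu$name),
    effect_window[1] < effect_window[2]
  )
  cfg <- list(
    n_patients = n_patients,
    surgeries_per_patient_rate = surgeries_per_patient_rate,
    prevalence_target = prevalence_target,
    surgery_length_meanlog = surgery_length_meanlog,
    surgery_length_sdlog = surgery_length_sdlog,
    surgery_length_range = surgery_length_range,
    feature_menu = feature_menu,
    effects = effects,
    effect_window = effect_window,
    static_menu = static_menu,
    patient_intercept_sd = patient_intercept_sd,
    noise_het_sd = noise_het_sd,
    nudesc_extra_rate = nudesc_extra_rate,
    nudesc_delay_mean = nudesc_delay_mean,
    nudesc_delay_sd = nudesc_delay_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_feature_menu <- function() {
  data.frame(
    name = c("hr", "nibp_map", "sef"),
    baseline_mean = c(75, 85, 14),
    baseline_sd = c(4, 6, 2),
    ar1_coef = c(0.6, 0.7, 0.7),
    noise_sd = c(5, 6, 1.5),
    obs_rate_per_min = c(1 / 3, 1 / 3, 1 / 3),
    stringsAsFactors = FALSE
  )
}

#' @rdname sim_config
#' @export
default_static_menu <- function() {
  data.frame(
    name = c("age", "asa"),
    base_mean = c(54, 2.2),
    base_sd = c(18, 0.8),
    delta_mean = c(7, 0.4),
    stringsAsFactors = FALSE
  )
}

# Deterministic per-unit stream: each patient/surgery gets its own seed derived
# from the global seed and its index, so extending the cohort never perturbs
# earlier units.
unit_seed <- function(seed, index, stream = 0L) {
  (as.double(seed) * 1000003 + index * 7919 + stream * 104729) %% 2147483647
}

#' Generate a synthetic perioperative cohort
#'
#' @param config a [sim_config()].
#' @param seed integer seed overriding `config$seed`.
#' @return list with `events` (long-format dynamic observations), `statics`
#'   (per-surgery static features), `nudesc` (recovery room assessments) and
#'   `truth` (per-surgery latent class, surgery lengths, the applied effect
#'   sizes and the patient-by-feature random intercepts).
#' @export
generate_cohort <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  menu <- config$feature_menu
  eff <- config$effects[match(menu$name, config$effects$feature), ]
  eff$delta_mean[is.na(eff$delta_mean)] <- 0
  eff$delta_slope_per_min[is.na(eff$delta_slope_per_min)] <- 0
  eff$delta_log_obs_rate[is.na(eff$delta_log_obs_rate)] <- 0
  k <- nrow(menu)

  # patient-level draws (own stream per patient)
  n_pat <- config$n_patients
  pat_ids <- sprintf("P%05d", seq_len(n_pat))
  intercepts <- matrix(0, n_pat, k, dimnames = list(pat_ids, menu$name))
  n_surg_per_pat <- integer(n_pat)
  static_base <- matrix(0, n_pat, nrow(config$static_menu),
                        dimnames = list(pat_ids, config$static_menu$name))
  for (p in seq_len(n_pat)) {
    local_seed(unit_seed(seed, p, 1L), {
      n_surg_per_pat[p] <- 1L + rpois(1, config$surgeries_per_patient_rate)
      intercepts[p, ] <- rnorm(k, 0, config$patient_intercept_sd)
      static_base[p, ] <- rnorm(nrow(config$static_menu),
                                config$static_menu$base_mean,
                                config$static_menu$base_sd)
    })
  }

  surg_pat <- rep(seq_len(n_pat), n_surg_per_pat)
  m <- length(surg_pat)
  surg_ids <- sprintf("S%06d", seq_len(m))

  ev_list <- vector("list", m)
  nu_list <- vector("list", m)
  Y <- integer(m)
  length_min <- numeric(m)
  st_vals <- matrix(0, m, nrow(config$static_menu),
                    dimnames = list(NULL, config$static_menu$name))
  mid <- mean(config$effect_window)
  w0 <- config$effect_window[1]
  w1 <- config$effect_window[2]

  for (s in seq_len(m)) {
    p <- surg_pat[s]
    local_seed(unit_seed(seed, s, 2L), {
      y <- rbinom(1, 1, config$prevalence_target)
      L <- exp(rnorm(1, config$surgery_length_meanlog,
                     config$surgery_length_sdlog))
      L <- min(max(L, config$surgery_length_range[1]),
               config$surgery_length_range[2])
      Y[s] <- y
      length_min[s] <- L
      # per-surgery measurement-noise heterogeneity (monitor/patient level)
      noise_fac <- exp(rnorm(1, 0, config$noise_het_sd))
      grid <- seq(0, ceiling(L))

      t_acc <- vector("list", k)
      v_acc <- vector("list", k)
      for (f in seq_len(k)) {
        phi <- menu$ar1_coef[f]
        sd_innov <- menu$baseline_sd[f] * sqrt(1 - phi^2)
        ar <- as.numeric(stats::filter(rnorm(length(grid), 0, sd_innov),
                                       phi, method = "recursive",
                                       init = rnorm(1, 0, menu$baseline_sd[f])))
        path <- menu$baseline_mean[f] + intercepts[p, f] + ar
        if (y == 1) {
          path <- path + eff$delta_mean[f]
          if (eff$delta_slope_per_min[f] != 0) {
            in_w <- grid >= w0 & grid <= w1
            path[in_w] <- path[in_w] +
              eff$delta_slope_per_min[f] * (grid[in_w] - mid)
          }
        }
        rate <- menu$obs_rate_per_min[f] *
          exp(if (y == 1) eff$delta_log_obs_rate[f] else 0)
        n_obs <- rpois(1, rate * L)
        if (n_obs > 0) {
          t_obs <- sort(runif(n_obs, 0, L))
          t_acc[[f]] <- t_obs
          v_acc[[f]] <- path[pmin(floor(t_obs) + 1L, length(path))] +
            rnorm(n_obs, 0, noise_fac * menu$noise_sd[f])
        }
      }
      n_per_feat <- lengths(t_acc)
      if (sum(n_per_feat) > 0) {
        ev_list[[s]] <- list(feature = rep(menu$name, n_per_feat),
                             t = unlist(t_acc), v = unlist(v_acc),
                             s = s)
      }

      # statics
      st_vals[s, ] <- static_base[p, ] + y * config$static_menu$delta_mean

      # Nu-DESC assessments in the recovery room
      n_ass <- 1L + rpois(1, config$nudesc_extra_rate)
      t_ass <- pmax(5, rnorm(n_ass, config$nudesc_delay_mean,
                             config$nudesc_delay_sd))
      cats <- matrix(0L, n_ass, 5)
      if (y == 1) {
        cats[] <- rbinom(n_ass * 5, 2, 0.15)
        if (sum(cats[1, ]) == 0) cats[1, sample.int(5, 1)] <- 1L
      }
      nu_list[[s]] <- list(t = sort(t_ass), cats = cats, s = s)
    })
  }

  ev_list <- ev_list[!vapply(ev_list, is.null, logical(1))]
  n_rows <- vapply(ev_list, function(e) length(e$t), integer(1))
  s_idx <- rep(vapply(ev_list, function(e) e$s, integer(1)), n_rows)
  events <- data.frame(
    surgery_id = surg_ids[s_idx],
    patient_id = pat_ids[surg_pat[s_idx]],
    feature_name = unlist(lapply(ev_list, `[[`, "feature")),
    t_offset_min = unlist(lapply(ev_list, `[[`, "t")),
    value = unlist(lapply(ev_list, `[[`, "v")),
    stringsAsFactors = FALSE
  )
  statics <- data.frame(surgery_id = surg_ids, patient_id = pat_ids[surg_pat],
                        st_vals, stringsAsFactors = FALSE)
  nu_rows <- vapply(nu_list, function(e) length(e$t), integer(1))
  nu_s <- rep(vapply(nu_list, function(e) e$s, integer(1)), nu_rows)
  nu_cats <- do.call(rbind, lapply(nu_list, `[[`, "cats"))
  nudesc <- data.frame(surgery_id = surg_ids[nu_s],
                       assess_time_min = unlist(lapply(nu_list, `[[`, "t")),
                       c1 = nu_cats[, 1], c2 = nu_cats[, 2],
                       c3 = nu_cats[, 3], c4 = nu_cats[, 4],
                       c5 = nu_cats[, 5], stringsAsFactors = FALSE)

  if (sum(Y) == 0) {
    warning("no POD-positive surgeries drawn at prevalence ",
            config$prevalence_target, " with ", m, " surgeries")
  }
  truth <- list(
    surgeries = data.frame(surgery_id = surg_ids,
                           patient_id = pat_ids[surg_pat],
                           Y = Y, length_min = length_min,
                           stringsAsFactors = FALSE),
    effects = config$effects,
    effect_window = config$effect_window,
    patient_intercepts = intercepts,
    seed = as.integer(seed)
  )
  list(events = events, statics = statics, nudesc = nudesc, truth = truth)
}

#' Cohorts with a single isolated class signal
#'
#' `make_mean_matched_slope_cohort()` builds the temporal-signal test bed: the
#' two classes differ only in the within-window slope of one designated signal
#' feature. Because the slope ramp is centred on the window midpoint, the
#' window mean is matched between classes by construction, so any classifier
#' restricted to order-invariant window summaries sees (almost) no signal,
#' while models that exploit temporal ordering can separate the classes.
#'
#' `make_missingness_cohort()` builds the informative-missingness test bed:
#' classes differ only in the Poisson observation rate of the signal feature
#' (values themselves carry no signal), so only models with access to
#' missingness-indicator channels can separate the classes.
#'
#' @param config a [sim_config()]; its `effects` are overridden.
#' @param signal_feature name of the feature carrying the effect.
#' @param delta_slope slope effect expressed in per-observation noise standard
#'   deviations per window length (converted internally to feature units per
#'   minute).
#' @param delta_log_obs_rate log observation-rate shift for POD-positive
#'   surgeries.
#' @param seed integer seed.
#' @return as [generate_cohort()].
#' @export
make_mean_matched_slope_cohort <- function(config = sim_config(),
                                           signal_feature = config$feature_menu$name[1],
                                           delta_slope = 1,
                                           seed = config$seed) {
  menu <- config$feature_menu
  f <- match(signal_feature, menu$name)
  if (is.na(f)) stop("unknown signal feature: ", signal_feature)
  w_len <- diff(config$effect_window)
  min_interval <- 1 / menu$obs_rate_per_min[f]
  if (w_len < 2 * min_interval) {
    stop("effect window shorter than 2 sampling intervals of the signal feature")
  }
  # per-observation noise sd: stationary AR(1) sd plus measurement noise
  obs_sd <- sqrt(menu$baseline_sd[f]^2 + menu$noise_sd[f]^2)
  eff <- data.frame(feature = menu$name, delta_mean = 0,
                    delta_slope_per_min = 0, delta_log_obs_rate = 0,
                    stringsAsFactors = FALSE)
  eff$delta_slope_per_min[f] <- delta_slope * obs_sd / w_len
  cfg <- config
  cfg$effects <- eff
  generate_cohort(cfg, seed = seed)
}

#' @rdname make_mean_matched_slope_cohort
#' @export
make_missingness_cohort <- function(config = sim_config(),
                                    signal_feature = config$feature_menu$name[1],
                                    delta_log_obs_rate = -0.9,
                                    seed = config$seed) {
  menu <- config$feature_menu
  f <- match(signal_feature, menu$name)
  if (is.na(f)) stop("unknown signal feature: ", signal_feature)
  eff <- data.frame(feature = menu$name, delta_mean = 0,
                    delta_slope_per_min = 0, delta_log_obs_rate = 0,
                    stringsAsFactors = FALSE)
  eff$delta_log_obs_rate[f] <- delta_log_obs_rate
  cfg <- config
  cfg$effects <- eff
  generate_cohort(cfg, seed = seed)
}

#' Write a generated cohort to CSV files plus a JSON truth sidecar
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$events, file.path(dir, "events.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$statics, file.path(dir, "statics.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$nudesc, file.path(dir, "nudesc.csv"),
                   row.names = FALSE, na = "")
  truth <- cohort$truth
  truth$patient_intercepts <- as.data.frame(truth$patient_intercepts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA)
  invisible(dir)
}

#' Simulate hierarchical window-summary data for mixed-model recovery
#'
#' Draws the mixed linear effects model's own generative process: per surgery
#' and window-index `time` (1-3),
#' `value = b0 + c_target * target + c_time * time + c_time_target * target *
#' time + u_patient + u_surgery + e`, with `u_patient ~ N(0, patient_sd^2)`
#' shared across a patient's surgeries, `u_surgery ~ N(0, surgery_sd^2)` and
#' i.i.d. residuals. The POD target is drawn per surgery at `prevalence`.
#' Used to verify fixed-effect recovery of the screening stage against known
#' truth.
#'
#' @param n_patients number of patients.
#' @param c_target,c_time,c_time_target true fixed effects.
#' @param b0 intercept.
#' @param patient_sd,surgery_sd,resid_sd variance components.
#' @param prevalence per-surgery POD probability.
#' @param surgeries_per_patient_rate Poisson rate of extra surgeries.
#' @param n_windows number of window indices per surgery.
#' @param seed integer seed.
#' @return `data.frame` with columns `value, target, time, pat_id, op_id`.
#' @export
simulate_mlem_data <- function(n_patients = 2000, c_target = 0.3,
                               c_time = 0, c_time_target = 0, b0 = 0.5,
                               patient_sd = 0.2, surgery_sd = 0.1,
                               resid_sd = 0.2, prevalence = 0.09,
                               surgeries_per_patient_rate = 0.19,
                               n_windows = 3L, seed = 1L) {
  local_seed(seed, {
    n_surg <- 1L + rpois(n_patients, surgeries_per_patient_rate)
    pat <- rep(seq_len(n_patients), n_surg)
    m <- length(pat)
    u_pat <- rnorm(n_patients, 0, patient_sd)
    u_surg <- rnorm(m, 0, surgery_sd)
    target <- rbinom(m, 1, prevalence)
    rows <- data.frame(
      pat_id = sprintf("P%05d", rep(pat, each = n_windows)),
      op_id = sprintf("S%06d", rep(seq_len(m), each = n_windows)),
      target = rep(target, each = n_windows),
      time = rep(seq_len(n_windows), m)
    )
    rows$value <- b0 + c_target * rows$target + c_time * rows$time +
      c_time_target * rows$target * rows$time +
      u_pat[rep(pat, each = n_windows)] +
      u_surg[rep(seq_len(m), each = n_windows)] +
      rnorm(nrow(rows), 0, resid_sd)
    rows
  })
}
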