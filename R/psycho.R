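# Familiar-baby recognition: the listener experiment design, a generative
# cohort simulator, a Bayesian logistic mixed model (JAGS) with random slopes
# for subjects and for the assigned (familiar) baby, posterior contrasts on
# the probability scale, and a machine-listener protocol that mirrors the
# human design with a two-class discriminant.

#' Listener experiment design
#'
#' Two training sessions of 5 discomfort cries from the assigned baby,
#' followed by a 20-trial test: 4 pain cries of the familiar baby and 4 pain
#' cries from each of 4 unknown babies (2 boys, 2 girls). Chance level is
#' 4/20 = 20%.
#'
#' @param n_training_sessions,cries_per_training,n_test_trials,
#'   n_familiar_test,n_unknown_babies,cries_per_unknown Design constants.
#' @return A list of class `experiment_design` (with `chance`).
#' @export
experiment_design <- function(n_training_sessions = 2L, cries_per_training = 5L,
                              n_test_trials = 20L, n_familiar_test = 4L,
                              n_unknown_babies = 4L, cries_per_unknown = 4L) {
  stopifnot(n_familiar_test + n_unknown_babies * cries_per_unknown == n_test_trials)
  structure(list(
    n_training_sessions = n_training_sessions,
    cries_per_training = cries_per_training,
    n_test_trials = n_test_trials,
    n_familiar_test = n_familiar_test,
    n_unknown_babies = n_unknown_babies,
    cries_per_unknown = cries_per_unknown,
    chance = n_familiar_test / n_test_trials
  ), class = "experiment_design")
}

#' Generative parameters for a simulated listener cohort
#'
#' @param hit_rate Population probability of a "yes" on familiar trials.
#' @param false_alarm_rate Population probability of a "yes" on unknown
#'   trials.
#' @param subject_sd,subject_slope_sd Logit-scale SDs of the per-subject
#'   intercept and familiar-status slope.
#' @param baby_sd,baby_slope_sd Logit-scale SDs of the per-assigned-baby
#'   intercept and status slope.
#' @param sex_logit,parent_logit Logit-scale group offsets (female minus
#'   male, parent minus non-parent; applied as half offsets per group).
#' @param seed Integer seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(hit_rate = 0.485, false_alarm_rate = 0.308,
                          subject_sd = 0.5, subject_slope_sd = 0.5,
                          baby_sd = 0.4, baby_slope_sd = 0.3,
                          sex_logit = 0, parent_logit = 0, seed = 1L) {
  stopifnot(hit_rate > 0, hit_rate < 1, false_alarm_rate > 0, false_alarm_rate < 1,
            subject_sd >= 0, subject_slope_sd >= 0, baby_sd >= 0, baby_slope_sd >= 0)
  structure(list(hit_rate = hit_rate, false_alarm_rate = false_alarm_rate,
                 subject_sd = subject_sd, subject_slope_sd = subject_slope_sd,
                 baby_sd = baby_sd, baby_slope_sd = baby_slope_sd,
                 sex_logit = sex_logit, parent_logit = parent_logit,
                 seed = as.integer(seed)), class = "cohort_params")
}

#' Simulate a listener cohort
#'
#' Default cohort mirrors the study: 100 subjects, 25 per sex x parental-
#' status cell, assigned cyclically to `n_babies` familiar babies; each
#' subject contributes 20 test trials (4 familiar). Responses are Bernoulli
#' draws from a logit model with subject (intercept + status slope) and
#' assigned-baby (intercept + status slope) random effects.
#'
#' @param design An [experiment_design()].
#' @param params A [cohort_params()].
#' @param n_subjects Total subjects (multiple of 4 for balanced cells).
#' @param n_babies Number of distinct familiar babies.
#' @return Tibble of trials: `subject_id`, `sex`, `parental_status`,
#'   `familiar_baby`, `stimulus_baby`, `real_status`, `response`, `order`.
#' @export
simulate_cohort <- function(design = experiment_design(),
                            params = cohort_params(),
                            n_subjects = 100L, n_babies = 9L) {
  per_cell <- n_subjects / 4
  subjects <- tibble(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    sex = rep(c("F", "M"), each = per_cell, times = 2),
    parental_status = rep(c("parent", "non-parent"), each = 2 * per_cell),
    familiar_baby = sprintf("FB%02d", (seq_len(n_subjects) - 1L) %% n_babies + 1L)
  )
  with_seed(params$seed, {
    u_s <- cbind(rnorm(n_subjects, 0, params$subject_sd),
                 rnorm(n_subjects, 0, params$subject_slope_sd))
    u_b <- cbind(rnorm(n_babies, 0, params$baby_sd),
                 rnorm(n_babies, 0, params$baby_slope_sd))
    # centre the realized random effects: with only a handful of assigned
    # babies their sample mean would otherwise shift the whole cohort's
    # rates away from the configured targets
    u_s <- scale(u_s, center = TRUE, scale = FALSE)
    u_b <- scale(u_b, center = TRUE, scale = FALSE)
    trials <- purrr::map(seq_len(n_subjects), function(i) {
      st <- c(rep("familiar", design$n_familiar_test),
              rep("unknown", design$n_test_trials - design$n_familiar_test))
      st <- sample(st)
      xs <- ifelse(st == "familiar", 0.5, -0.5)
      b <- (i - 1L) %% n_babies + 1L
      xx <- if (subjects$sex[i] == "F") 0.5 else -0.5
      xp <- if (subjects$parental_status[i] == "parent") 0.5 else -0.5
      base <- ifelse(st == "familiar", qlogis(params$hit_rate),
                     qlogis(params$false_alarm_rate))
      eta <- base + params$sex_logit * xx + params$parent_logit * xp +
        u_s[i, 1] + u_s[i, 2] * xs + u_b[b, 1] + u_b[b, 2] * xs
      tibble(subject_id = subjects$subject_id[i],
             sex = subjects$sex[i],
             parental_status = subjects$parental_status[i],
             familiar_baby = subjects$familiar_baby[i],
             stimulus_baby = ifelse(st == "familiar", subjects$familiar_baby[i],
                                    sprintf("UB%02d", sample.int(40L, design$n_test_trials,
                                                                 replace = TRUE))),
             real_status = st,
             response = rbinom(design$n_test_trials, 1L, plogis(eta)),
             order = seq_len(design$n_test_trials))
    })
    bind_rows(trials)
  })
}

#' MCMC configuration for the listener model
#'
#' The default mirrors the reported analysis: 2 chains of 3000 iterations
#' with the first 1000 used for adaptation. `listener_mcmc_fast()` is a
#' reduced profile for quick runs.
#'
#' @param chains,iter,warmup MCMC dimensions (`iter` includes `warmup`).
#' @param seed Integer seed for the samplers.
#' @return A list of class `listener_mcmc`.
#' @export
listener_mcmc <- function(chains = 2L, iter = 3000L, warmup = 1000L, seed = 1L) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 100)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "listener_mcmc")
}

#' @rdname listener_mcmc
#' @export
listener_mcmc_fast <- function(seed = 1L) listener_mcmc(2L, 1100L, 400L, seed)

.listener_jags_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbern(p[i])
    # subject intercepts are hierarchically centred on the population
    # intercept beta[1] (better mixing than the zero-centred form)
    logit(p[i]) <- a_subj[subj[i]] + inprod(X[i, 2:8], beta[2:8]) +
      us2[subj[i]] * xs[i] +
      ub[baby[i], 1] + ub[baby[i], 2] * xs[i] + ub[baby[i], 3] * xp[i]
  }
  beta[1] ~ dnorm(mu0, 1)
  for (k in 2:8) { beta[k] ~ dnorm(0, 1) }
  for (s in 1:S) {
    a_subj[s] ~ dnorm(beta[1], tau_s[1])
    us2[s] ~ dnorm(0, tau_s[2])
  }
  for (b in 1:B) {
    for (k in 1:3) { ub[b, k] ~ dnorm(0, tau_b[k]) }
  }
  for (k in 1:2) { sigma_s[k] ~ dnorm(0, 1) T(0,) ; tau_s[k] <- pow(sigma_s[k], -2) }
  for (k in 1:3) { sigma_b[k] ~ dnorm(0, 1) T(0,) ; tau_b[k] <- pow(sigma_b[k], -2) }
}
"

#' Fit the Bayesian logistic mixed model of listener responses
#'
#' Models the binary yes/no response with fixed effects for real baby status,
#' listener sex, parental status and all their interactions (sum-to-zero
#' +/- 0.5 coding, so each coefficient is a full logit-scale contrast), random
#' intercept and status slope per subject, and random intercept, status slope
#' and parentality slope per assigned baby. Priors are Normal(0, 1) on effect
#' coefficients and Normal(logit(chance), 1) on the intercept. Posterior
#' rates are reported on the probability scale for the population-median
#' subject and baby (random effects at zero), averaged over design cells.
#'
#' @param trials Trials tibble as produced by [simulate_cohort()] (columns
#'   `subject_id`, `sex`, `parental_status`, `familiar_baby`, `real_status`,
#'   `response`).
#' @param mcmc A [listener_mcmc()] configuration.
#' @param chance Chance level used to center the intercept prior.
#' @return A `listener_fit`: `summaries` tibble (median and 95% credible
#'   interval per quantity), posterior `draws`, convergence diagnostics
#'   (`max_rhat`, `converged`), and the model dimensions.
#' @export
fit_listener_model <- function(trials, mcmc = listener_mcmc(),
                               chance = 0.20) {
  needed <- c("subject_id", "sex", "parental_status", "familiar_baby",
              "real_status", "response")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    abort(paste0("trials table lacks: ", paste(missing_cols, collapse = ", ")))
  }
  xs <- ifelse(trials$real_status == "familiar", 0.5, -0.5)
  xp <- ifelse(trials$parental_status == "parent", 0.5, -0.5)
  xx <- ifelse(trials$sex == "F", 0.5, -0.5)
  X <- cbind(1, xs, xp, xx, xs * xp, xs * xx, xp * xx, xs * xp * xx)
  subj <- as.integer(factor(trials$subject_id))
  baby <- as.integer(factor(trials$familiar_baby))
  data <- list(y = as.integer(trials$response), X = X, xs = xs, xp = xp,
               N = nrow(trials), S = max(subj), B = max(baby),
               subj = subj, baby = baby, mu0 = qlogis(chance))
  inits <- lapply(seq_len(mcmc$chains), function(c) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = mcmc$seed + c)
  })
  jm <- rjags::jags.model(textConnection(.listener_jags_model), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = mcmc$warmup, quiet = TRUE)
  samp <- rjags::coda.samples(jm, c("beta", "sigma_s", "sigma_b"),
                              n.iter = mcmc$iter - mcmc$warmup)
  cell_rate_of <- function(beta, s_val, p_vals = c(0.5, -0.5),
                           x_vals = c(0.5, -0.5)) {
    acc <- 0
    for (pv in p_vals) for (xv in x_vals) {
      Xc <- c(1, s_val, pv, xv, s_val * pv, s_val * xv, pv * xv, s_val * pv * xv)
      acc <- acc + plogis(as.numeric(beta %*% Xc))
    }
    acc / (length(p_vals) * length(x_vals))
  }
  # convergence is diagnosed on the reported rate quantities, per chain
  rhat <- tryCatch({
    per_chain <- lapply(samp, function(ch) {
      b <- as.matrix(ch)[, paste0("beta[", 1:8, "]"), drop = FALSE]
      coda::mcmc(cbind(rec = cell_rate_of(b, 0.5),
                       fa = cell_rate_of(b, -0.5)))
    })
    max(coda::gelman.diag(coda::as.mcmc.list(per_chain), autoburnin = FALSE,
                          multivariate = FALSE)$psrf[, 1])
  }, error = function(e) NA_real_)
  draws <- as.matrix(samp)
  beta <- draws[, paste0("beta[", 1:8, "]"), drop = FALSE]
  cell_rate <- function(s_val, p_vals = c(0.5, -0.5), x_vals = c(0.5, -0.5)) {
    cell_rate_of(beta, s_val, p_vals, x_vals)
  }
  recognition <- cell_rate(0.5)
  false_positive <- cell_rate(-0.5)
  rec_f <- cell_rate(0.5, x_vals = 0.5)
  rec_m <- cell_rate(0.5, x_vals = -0.5)
  rec_par <- cell_rate(0.5, p_vals = 0.5)
  rec_non <- cell_rate(0.5, p_vals = -0.5)
  qtl <- function(v) unname(quantile(v, c(0.5, 0.025, 0.975)))
  summaries <- bind_rows(
    tibble(quantity = "recognition", !!!setNames(as.list(qtl(recognition)),
                                                 c("median", "ci_lower", "ci_upper"))),
    tibble(quantity = "false_positive", !!!setNames(as.list(qtl(false_positive)),
                                                    c("median", "ci_lower", "ci_upper"))),
    tibble(quantity = "familiar_vs_unknown",
           !!!setNames(as.list(qtl(recognition - false_positive)),
                       c("median", "ci_lower", "ci_upper"))),
    tibble(quantity = "sex_contrast", !!!setNames(as.list(qtl(rec_f - rec_m)),
                                                  c("median", "ci_lower", "ci_upper"))),
    tibble(quantity = "parentality_contrast",
           !!!setNames(as.list(qtl(rec_par - rec_non)),
                       c("median", "ci_lower", "ci_upper")))
  )
  structure(list(
    summaries = summaries,
    draws = draws,
    quantities = list(recognition = recognition, false_positive = false_positive),
    max_rhat = rhat,
    converged = is.finite(rhat) && rhat < 1.1,
    n_subjects = max(subj), n_babies = max(baby), n_trials = nrow(trials),
    mcmc = mcmc, chance = chance
  ), class = "listener_fit")
}

#' @export
print.listener_fit <- function(x, ...) {
  cat(sprintf("<listener_fit> %d trials, %d subjects, %d familiar babies; max Rhat %.3f%s\n",
              x$n_trials, x$n_subjects, x$n_babies, x$max_rhat,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(x$summaries)
  invisible(x)
}

#' @export
tidy.listener_fit <- function(x, ...) x$summaries

#' @export
glance.listener_fit <- function(x, ...) {
  tibble(recognition = x$summaries$median[x$summaries$quantity == "recognition"],
         false_positive = x$summaries$median[x$summaries$quantity == "false_positive"],
         max_rhat = x$max_rhat, converged = x$converged,
         n_trials = x$n_trials)
}

#' Posterior contrasts on the probability scale
#'
#' @param fit A `listener_fit`.
#' @return Tibble of the pairwise contrasts with medians, 95% credible
#'   intervals, and a `credible` flag (interval excludes 0).
#' @export
contrast_summaries <- function(fit) {
  stopifnot(inherits(fit, "listener_fit"))
  fit$summaries %>%
    filter(.data$quantity %in% c("familiar_vs_unknown", "sex_contrast",
                                 "parentality_contrast")) %>%
    mutate(credible = .data$ci_lower > 0 | .data$ci_upper < 0)
}

#' Machine-listener protocol
#'
#' Mirrors the human experiment with a two-class linear discriminant: for
#' each candidate familiar baby (>= 10 discomfort cries and >= 4 pain cries),
#' the classifier is trained on 10 of the baby's discomfort cries against the
#' other babies' discomfort cries (on the first `n_components` MPS PCs,
#' fitted on the training set), then applied to a 20-cry test set of 4
#' familiar pain cries and 4 pain cries from each of 4 unknown babies (2
#' boys, 2 girls when available). Class priors are set to the test
#' prevalence (20% familiar), the same base rate human listeners faced.
#'
#' @param mps_set An `mps_set` for the corpus.
#' @param design An [experiment_design()].
#' @param seed Integer seed (training-cry and unknown-baby sampling).
#' @param n_components PCs retained.
#' @return A `machine_listener_result`: per-familiar-baby tibble with
#'   `hit_rate` and `false_alarm_rate`, plus summary means with 2 SE.
#' @export
machine_listener <- function(mps_set, design = experiment_design(), seed = 1L,
                             n_components = 20L) {
  stopifnot(inherits(mps_set, "mps_set"))
  meta <- mps_set$meta
  counts <- meta %>% count(.data$baby_id, .data$condition) %>%
    tidyr::pivot_wider(names_from = "condition", values_from = "n", values_fill = 0L)
  fam_ok <- counts$baby_id[counts$discomfort >= 2 * design$cries_per_training &
                             counts$pain >= design$n_familiar_test]
  unk_ok <- counts$baby_id[counts$pain >= design$cries_per_unknown]
  if (length(fam_ok) == 0) {
    abort(sprintf("no baby has >= %d discomfort and >= %d pain cries",
                  2 * design$cries_per_training, design$n_familiar_test))
  }
  sex_of <- meta %>% distinct(.data$baby_id, .data$sex)
  rows <- with_seed(seed, purrr::map(fam_ok, function(fb) {
    pool <- setdiff(unk_ok, fb)
    pool_sex <- sex_of$sex[match(pool, sex_of$baby_id)]
    boys <- pool[pool_sex == "M"]
    girls <- pool[pool_sex == "F"]
    n_half <- design$n_unknown_babies %/% 2L
    unknown <- c(
      if (length(boys) >= n_half) sample(boys, n_half) else boys,
      if (length(girls) >= n_half) sample(girls, n_half) else girls)
    if (length(unknown) < design$n_unknown_babies) {
      extra <- setdiff(pool, unknown)
      unknown <- c(unknown, sample(extra, design$n_unknown_babies - length(unknown)))
    }
    disc_f <- which(meta$baby_id == fb & meta$condition == "discomfort")
    train_f <- sample(disc_f, 2L * design$cries_per_training)
    train_o <- which(meta$baby_id != fb & meta$condition == "discomfort")
    test_f <- sample(which(meta$baby_id == fb & meta$condition == "pain"),
                     design$n_familiar_test)
    test_u <- unlist(lapply(unknown, function(u) {
      sample(which(meta$baby_id == u & meta$condition == "pain"),
             design$cries_per_unknown)
    }))
    tr <- c(train_f, train_o)
    te <- c(test_f, test_u)
    basis <- fit_mps_pca(mps_set$X[tr, , drop = FALSE], n_components,
                         fitted_on = "machine-listener training")
    xtr <- project_mps(basis, mps_set$X[tr, , drop = FALSE])
    xte <- project_mps(basis, mps_set$X[te, , drop = FALSE])
    lab <- factor(c(rep("familiar", length(train_f)),
                    rep("other", length(train_o))), levels = c("familiar", "other"))
    fit <- MASS::lda(xtr, grouping = lab,
                     prior = c(design$chance, 1 - design$chance))
    post <- predict(fit, xte)$posterior[, "familiar"]
    yes <- post > 0.5
    truth <- c(rep(TRUE, length(test_f)), rep(FALSE, length(test_u)))
    tibble(familiar_baby = fb,
           hit_rate = mean(yes[truth]),
           false_alarm_rate = mean(yes[!truth]),
           percent_correct = mean(yes == truth))
  }) %>% bind_rows())
  two_se <- function(v) 2 * sd(v) / sqrt(length(v))
  structure(list(
    per_baby = rows,
    hit_rate = mean(rows$hit_rate), hit_rate_2se = two_se(rows$hit_rate),
    false_alarm_rate = mean(rows$false_alarm_rate),
    false_alarm_2se = two_se(rows$false_alarm_rate),
    percent_correct = mean(rows$percent_correct),
    chance = design$chance
  ), class = "machine_listener_result")
}

#' @export
print.machine_listener_result <- function(x, ...) {
  cat(sprintf(
    "<machine_listener_result> %d familiar babies: hits %.1f%% +/- %.1f%% [2SE], false alarms %.1f%% (chance %.0f%%)\n",
    nrow(x$per_baby), 100 * x$hit_rate, 100 * x$hit_rate_2se,
    100 * x$false_alarm_rate, 100 * x$chance))
  invisible(x)
}

#' @export
glance.machine_listener_result <- function(x, ...) {
  tibble(hit_rate = x$hit_rate, hit_rate_2se = x$hit_rate_2se,
         false_alarm_rate = x$false_alarm_rate,
         false_alarm_2se = x$false_alarm_2se,
         percent_correct = x$percent_correct,
         n_familiar = nrow(x$per_baby), chance = x$chance)
}
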