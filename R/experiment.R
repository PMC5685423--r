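EXPERIMENT_DESIGNS <- list(
  `1` = list(conditions = c("static_static", "smooth_static"),
             densities = c(0, 0.5, 0.75)),
  `2` = list(conditions = c("static_updating", "smooth_updating"),
             densities = c(0.5, 0.75)),
  `3` = list(conditions = c("static_smoothmask", "smooth_static"),
             densities = c(0.5, 0.75)),
  `4` = list(conditions = c("shuffled_static", "smooth_static"),
             densities = c(0.5, 0.75))
)

#' Simulated subject pool
#'
#' Draws a panel of model observers around a base parameterization, with
#' per-subject lognormal jitter (default +/- ~20%) on the front-end blur
#' and internal noise, emulating individual differences across the eight
#' observers of the study design.
#'
#' @param n_subjects number of subjects.
#' @param base an [observer_params()] giving the population center.
#' @param jitter_sdlog lognormal SD of the per-subject multiplier.
#' @param seed integer seed.
#' @return a list of subject models, each with `subject_id`, `params`,
#'   `seed`.
#' @export
subject_models <- function(n_subjects = 8, base = observer_params(),
                           jitter_sdlog = 0.2, seed = 1L) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    mult <- with_seed(derive_seed(seed, i), exp(rnorm(2, 0, jitter_sdlog)))
    params <- base
    params$blur_sigma <- base$blur_sigma * mult[1]
    params$noise_sd <- base$noise_sd * mult[2]
    list(subject_id = sprintf("s%d", i), params = params,
         seed = derive_seed(seed, i, 999L))
  })
}

#' Run all staircase runs of one condition for one subject
#'
#' Executes `n_runs` independent staircases (distinct derived seeds),
#' pools the trial records across runs, and fits the psychometric
#' function to the pooled data.
#'
#' @param subject a subject model from [subject_models()].
#' @param condition_label one of `conditions()$label`.
#' @param density mask density in \[0, 1\].
#' @param n_runs number of staircase runs (>= 1).
#' @param seed integer seed (combined with the subject's own seed).
#' @param display a [display_model()].
#' @param staircase template [init_staircase()] state.
#' @param fit logical: attach the pooled ML fit?
#' @return list with `trials` (pooled tibble) and `fit` (a
#'   `psychometric_fit` or `NULL`).
#' @export
run_condition <- function(subject, condition_label, density, n_runs = 10,
                          seed = 1L, display = display_model(),
                          staircase = init_staircase(), fit = TRUE) {
  if (!is.numeric(n_runs) || n_runs < 1)
    stop("n_runs must be >= 1")
  cond <- condition_spec(condition_label, density)
  cond_idx <- match(condition_label, CONDITION_LABELS)
  dens_idx <- round(density * 100)
  runs <- lapply(seq_len(n_runs), function(r) {
    run_seed <- derive_seed(subject$seed, seed, cond_idx, dens_idx, r)
    run_staircase(cond, subject$params, seed = run_seed, display = display,
                  staircase = staircase, subject_id = subject$subject_id,
                  run_id = r)
  })
  trials <- do.call(rbind, runs)
  fit_obj <- NULL
  if (fit) {
    fit_obj <- tryCatch(fit_ml(trials), error = function(e) {
      warning(sprintf("fit failed for %s/%s/%.2f: %s", subject$subject_id,
                      condition_label, density, conditionMessage(e)))
      NULL
    })
  }
  list(trials = trials, fit = fit_obj)
}

#' Run a full simulated experiment
#'
#' Orchestrates one of the four experiments over the subject panel:
#' every subject completes every condition x density cell (`n_runs`
#' staircases per cell), and the pooled threshold estimate for each cell
#' goes into the results table.
#'
#' @param experiment experiment number 1-4 (selects the condition pair and
#'   density set), or a list with `conditions` and `densities` for a
#'   custom design.
#' @param subjects subject panel from [subject_models()].
#' @param n_runs staircase runs per cell.
#' @param seed integer master seed.
#' @param display a [display_model()].
#' @param staircase template staircase state.
#' @param keep_trials logical: attach all pooled trial records as
#'   attribute `"trials"`.
#' @param progress logical: print per-cell progress.
#' @return a results tibble with one row per (subject, condition, density):
#'   columns `subject`, `condition`, `density`, `mu`, `sigma`, `n_trials`.
#' @export
run_experiment <- function(experiment, subjects = subject_models(),
                           n_runs = 10, seed = 1L,
                           display = display_model(),
                           staircase = init_staircase(),
                           keep_trials = FALSE, progress = FALSE) {
  design <- if (is.list(experiment)) experiment
            else EXPERIMENT_DESIGNS[[as.character(experiment)]]
  if (is.null(design))
    stop("unknown experiment: ", experiment)
  if (length(subjects) == 0) stop("empty subject list")
  rows <- list()
  all_trials <- list()
  for (s in subjects) {
    for (cl in design$conditions) {
      for (d in design$densities) {
        if (progress)
          message(sprintf("subject %s | %s | density %.2f",
                          s$subject_id, cl, d))
        res <- run_condition(s, cl, d, n_runs = n_runs, seed = seed,
                             display = display, staircase = staircase)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = s$subject_id, condition = cl, density = d,
          mu = if (is.null(res$fit)) NA_real_ else res$fit$mu,
          sigma = if (is.null(res$fit)) NA_real_ else res$fit$sigma,
          n_trials = nrow(res$trials))
        if (keep_trials) all_trials[[length(all_trials) + 1]] <- res$trials
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "design") <- design
  if (keep_trials) attr(out, "trials") <- do.call(rbind, all_trials)
  out
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subjects two-factor ANOVA on a balanced results table (one
#' observation per subject x A x B cell). Each effect is tested against
#' its own effect-by-subject interaction: `F = MS_effect /
#' MS_(effect x subject)`, the standard univariate repeated-measures
#' partition. The full sums-of-squares decomposition is returned and must
#' conserve the total sum of squares.
#'
#' @param table results tibble (e.g. from [run_experiment()]).
#' @param dv name of the dependent-variable column (default `"mu"`).
#' @param factor_a,factor_b,subject column names of the two within-subject
#'   factors and the subject identifier.
#' @return an object of class `anova_rm2`: a tibble with one row per
#'   source (`A`, `B`, `A:B`, their subject interactions, subject,
#'   residual-free total) carrying `ss`, `df`, `ms`, `F`, `p`.
#' @export
rm_anova_2way <- function(table, dv = "mu", factor_a = "condition",
                          factor_b = "density", subject = "subject") {
  y <- table[[dv]]
  A <- factor(table[[factor_a]])
  B <- factor(table[[factor_b]])
  S <- factor(table[[subject]])
  if (any(is.na(y))) stop("missing values in the dependent variable")
  a <- nlevels(A); b <- nlevels(B); s <- nlevels(S)
  if (s < 2) stop("need at least 2 subjects")
  counts <- table(A, B, S)
  if (any(counts != 1))
    stop("design must be balanced with one observation per cell")
  gm <- mean(y)
  m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_s <- tapply(y, S, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, S), mean)
  m_bs <- tapply(y, list(B, S), mean)
  ss_a <- b * s * sum((m_a - gm)^2)
  ss_b <- a * s * sum((m_b - gm)^2)
  ss_s <- a * b * sum((m_s - gm)^2)
  ss_ab <- s * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + gm)^2)
  ss_as <- b * sum((m_as - outer(m_a, rep(1, s)) -
                      outer(rep(1, a), m_s) + gm)^2)
  ss_bs <- a * sum((m_bs - outer(m_b, rep(1, s)) -
                      outer(rep(1, b), m_s) + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  df_a <- a - 1; df_b <- b - 1; df_s <- s - 1
  df_ab <- df_a * df_b; df_as <- df_a * df_s; df_bs <- df_b * df_s
  df_abs <- df_a * df_b * df_s
  eff <- tibble::tibble(
    source = c("A", "B", "A:B", "subject", "A:subject", "B:subject",
               "A:B:subject"),
    ss = c(ss_a, ss_b, ss_ab, ss_s, ss_as, ss_bs, ss_abs),
    df = c(df_a, df_b, df_ab, df_s, df_as, df_bs, df_abs))
  eff$ms <- eff$ss / eff$df
  err_ms <- c(eff$ms[5], eff$ms[6], eff$ms[7], NA, NA, NA, NA)
  err_df <- c(df_as, df_bs, df_abs, NA, NA, NA, NA)
  eff$F <- eff$ms / err_ms
  eff$p <- stats::pf(eff$F, eff$df, err_df, lower.tail = FALSE)
  structure(list(effects = eff, ss_total = ss_tot,
                 factors = c(A = factor_a, B = factor_b),
                 n_subjects = s),
            class = "anova_rm2")
}

#' @export
print.anova_rm2 <- function(x, ...) {
  cat(sprintf("Two-way repeated-measures ANOVA (A = %s, B = %s, %d subjects)\n",
              x$factors["A"], x$factors["B"], x$n_subjects))
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' Per-density motion-benefit contrast
#'
#' For a two-condition results table, computes at each density the mean
#' over subjects of the threshold difference (first condition minus
#' second, in the order given by `conditions` or the table's factor
#' order), with a percentile bootstrap CI over subjects.
#'
#' @param table results tibble with exactly two condition levels.
#' @param conditions optional length-2 character giving the order of the
#'   contrast (`diff = conditions[1] - conditions[2]`).
#' @param n_boot bootstrap resamples over subjects.
#' @param seed integer seed.
#' @return tibble with one row per density: `density`, `difference`,
#'   `ci_lo`, `ci_hi`, `n_subjects`.
#' @export
motion_benefit <- function(table, conditions = NULL, n_boot = 2000,
                           seed = 1L) {
  conds <- unique(table$condition)
  if (is.null(conditions)) conditions <- conds
  if (length(conditions) != 2 || !all(conditions %in% conds))
    stop("table must contain exactly the two contrasted conditions")
  densities <- sort(unique(table$density))
  rows <- lapply(densities, function(d) {
    t1 <- table[table$density == d & table$condition == conditions[1], ]
    t2 <- table[table$density == d & table$condition == conditions[2], ]
    t1 <- t1[order(t1$subject), ]; t2 <- t2[order(t2$subject), ]
    if (nrow(t1) != nrow(t2) || !all(t1$subject == t2$subject))
      stop("missing cells: conditions are not matched over subjects")
    diffs <- t1$mu - t2$mu
    ns <- length(diffs)
    ci <- if (ns > 1) {
      boots <- with_seed(derive_seed(seed, round(d * 100)), {
        vapply(seq_len(n_boot), function(b)
          mean(diffs[sample.int(ns, ns, replace = TRUE)]), numeric(1))
      })
      unname(stats::quantile(boots, c(0.025, 0.975)))
    } else c(NA_real_, NA_real_)
    tibble::tibble(density = d, difference = mean(diffs),
                   ci_lo = ci[1], ci_hi = ci[2], n_subjects = ns)
  })
  out <- do.call(rbind, rows)
  attr(out, "contrast") <- conditions
  out
}

#' Threshold-versus-density summary figure
#'
#' Mean size threshold (+/- SEM over subjects) as a function of mask
#' density, one line per condition — the standard layout for reporting
#' these experiments. Requires ggplot2.
#'
#' @param table results tibble from [run_experiment()].
#' @return a ggplot object.
#' @export
plot_thresholds <- function(table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  agg <- stats::aggregate(mu ~ condition + density, data = table,
                          FUN = mean)
  agg$se <- stats::aggregate(mu ~ condition + density, data = table,
                             FUN = function(v) sd(v) / sqrt(length(v)))$mu
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(density), y = mu,
                                    fill = condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = mu - se, ymax = mu + se),
      position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = "Mask density", y = "Size threshold (arcmin)",
                  fill = "Condition") +
    ggplot2::theme_classic()
}
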