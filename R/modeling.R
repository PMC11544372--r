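# Mixed-model inference protocol for the register x age x parent-gender
# design: eight model families sharing one fixed-effects skeleton
# (register, z-scored child age, parent gender and their interactions up to
# order three, plus control covariates), a full-null likelihood-ratio
# comparison that guards against cryptic multiple testing, and iterative
# pruning of non-significant interactions.
#
# Estimation is maximum likelihood throughout (lme4 for Gaussian and Poisson
# families, glmmTMB for the beta family); significance of individual terms
# uses likelihood-ratio drop-one tests for every family.

MEASURE_FAMILIES <- tibble::tibble(
  family_id = 1:8,
  measure = c("pitch", "pitch_range", "articulation_rate", "vowel_duration",
              "vowel_space_corner", "vowel_space_full", "vowel_variability",
              "vowel_distinctiveness"),
  level = c("phrases", "phrases", "phrases", "tokens", "sessions",
            "sessions", "variability", "sessions"),
  error_family = c("gaussian", "gaussian", "poisson", "gaussian", "gaussian",
                   "gaussian", "gaussian", "beta")
)

#' Specification of one of the eight model families
#'
#' Families: 1 pitch (semitones), 2 pitch range (semitones), 3 articulation
#' rate (Poisson syllable count with log phonation-time offset), 4 vowel
#' duration (log ms after 10 ms rounding), 5/6 corner/full vowel-space area
#' (Hz^2), 7 vowel variability (log Hz^2), 8 vowel distinctiveness (beta
#' family, logit link).
#'
#' The fixed-effects skeleton is shared: register, z-scored child age,
#' parent gender and their interactions up to order three, plus child
#' gender, recording order and the child-by-parent gender interaction;
#' phrase-level families (1-3) additionally carry z-scored phrase onset and
#' its two-way interactions with the target terms. The null specification
#' equals the full one minus register and every interaction containing
#' register.
#'
#' The default random structure uses intercepts for family, parent and
#' session-in-family plus an uncorrelated register slope within family
#' (word and vowel-category intercepts where the response is token- or
#' category-level); richer slope structures can be supplied via `random`.
#'
#' @param family_id Integer 1-8.
#' @param random Optional random-effects formula string overriding the
#'   default (e.g. `"(1 | family_id)"`).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec(1)
model_spec <- function(family_id, random = NULL) {
  if (!family_id %in% 1:8) {
    stop_config("family_id must be an integer in 1..8")
  }
  fam <- MEASURE_FAMILIES[MEASURE_FAMILIES$family_id == family_id, ]
  onset <- family_id %in% 1:3
  targets <- c("register", "age_z", "parent_gender")
  fixed <- c(
    targets,
    "register:age_z", "register:parent_gender", "age_z:parent_gender",
    "register:age_z:parent_gender",
    "child_gender", "recording_order", "parent_gender:child_gender"
  )
  if (onset) {
    fixed <- c(fixed, "onset_z", "onset_z:register", "onset_z:age_z",
               "onset_z:parent_gender")
  }
  if (is.null(random)) {
    random <- "(1 | family_id) + (0 + register_num | family_id) + (1 | speaker_id) + (1 | session_cell)"
    if (family_id == 4) {
      random <- paste(random, "+ (1 | word) + (1 | category)")
    }
    if (family_id == 7) {
      random <- paste(random, "+ (1 | category)")
    }
    if (family_id %in% c(5, 6, 8)) {
      random <- "(1 | family_id) + (0 + register_num | family_id) + (1 | speaker_id)"
    }
  }
  structure(
    list(
      family_id = family_id,
      measure = fam$measure,
      level = fam$level,
      error_family = fam$error_family,
      fixed = order_terms(fixed),
      offset = if (family_id == 3) "log_phonation" else NULL,
      random = random,
      response = "response"
    ),
    class = "model_spec"
  )
}

term_order <- function(terms) {
  lengths(strsplit(terms, ":", fixed = TRUE))
}

# Deterministic term ordering: by interaction order, then lexicographic --
# makes pruning traces reproducible.
order_terms <- function(terms) {
  terms[order(term_order(terms), terms)]
}

term_contained_in <- function(a, b) {
  ca <- strsplit(a, ":", fixed = TRUE)[[1]]
  cb <- strsplit(b, ":", fixed = TRUE)[[1]]
  length(ca) < length(cb) && all(ca %in% cb)
}

null_terms <- function(terms) {
  terms[!vapply(strsplit(terms, ":", fixed = TRUE),
                function(p) "register" %in% p, logical(1))]
}

z_score <- function(x, column) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop_config("covariate '%s' has zero variance; cannot z-transform", column)
  }
  (x - mean(x)) / s
}

#' Round to the nearest 10 ms and log-transform a duration
#'
#' Vowel durations are rounded to the nearest 10 ms before the log
#' transform, absorbing sub-step differences between manually and
#' automatically placed boundaries.
#'
#' @param duration_ms Durations in milliseconds.
#' @return `log(round(duration_ms / 10) * 10)`.
#' @export
#' @examples
#' log_round10(127)  # log(130)
log_round10 <- function(duration_ms) {
  r <- round(duration_ms / 10) * 10
  if (any(r <= 0)) {
    stop_config("durations must round to a positive number of ms")
  }
  log(r)
}

#' Prepare a measure table for model fitting
#'
#' Builds the response on its modelling scale, drops rows where it is
#' undefined, recodes the design factors with their reference levels (ADS,
#' father, boy, ADS-first), z-transforms the quantitative covariates on the
#' analysis sample, and records the centring constants as attributes
#' (`age_center`, `age_scale`, and `onset_center`/`onset_scale` where
#' phrase onset is used) for back-transformation.
#'
#' Responses per family: 1 `pitch_st`; 2 `pitch_range_st`; 3 syllable count
#' (with `log_phonation` offset; rows need `phonation_time > 0`); 4
#' `log(round10(duration_ms))`; 5/6 vowel-space areas; 7 log variability;
#' 8 distinctiveness, shrunk from the \{0, 1\} boundaries by
#' `(y (n - 1) + 1/2) / n` when boundary values occur.
#'
#' @param data Measure table at the level `spec$level` (see
#'   [summarize_sessions()]).
#' @param spec A [model_spec()].
#' @return A tibble ready for [fit_model()].
#' @export
prepare_covariates <- function(data, spec) {
  d <- tibble::as_tibble(data)
  fid <- spec$family_id
  if (fid %in% 1:2 && !"pitch_st" %in% names(d)) {
    d <- add_pitch_measures(d)
  }
  resp <- switch(as.character(fid),
    "1" = d$pitch_st,
    "2" = d$pitch_range_st,
    "3" = d$n_syllables,
    "4" = log_round10(d$duration_ms),
    "5" = d$vowel_space_corner,
    "6" = d$vowel_space_full,
    "7" = log(d$variability),
    "8" = d$distinctiveness
  )
  d$response <- resp
  keep <- is.finite(d$response)
  if (fid == 3) {
    keep <- keep & d$phonation_time > 0
    d$log_phonation <- log(pmax(d$phonation_time, .Machine$double.xmin))
  }
  dropped <- sum(!keep)
  if (dropped > 0) {
    message(dropped, " row(s) without a defined response dropped before fitting")
  }
  d <- d[keep, , drop = FALSE]
  if (fid == 8) {
    if (any(d$response <= 0 | d$response >= 1)) {
      n <- nrow(d)
      d$response <- (d$response * (n - 1) + 0.5) / n
    }
  }
  d$register <- factor(d$register, levels = c("ADS", "IDS"))
  d$register_num <- as.numeric(d$register == "IDS")
  d$parent_gender <- factor(d$parent_gender, levels = c("father", "mother"))
  d$child_gender <- factor(d$child_gender, levels = c("boy", "girl"))
  d$recording_order <- factor(d$recording_order,
                              levels = c("ads_first", "ids_first"))
  d$session_cell <- interaction(d$family_id, d$session, drop = TRUE)
  d$age_z <- z_score(d$child_age_days, "child_age_days")
  attr(d, "age_center") <- mean(data$child_age_days[keep])
  attr(d, "age_scale") <- stats::sd(data$child_age_days[keep])
  if (spec$family_id %in% 1:3) {
    d$onset_z <- z_score(d$onset, "onset")
    attr(d, "onset_center") <- mean(d$onset)
    attr(d, "onset_scale") <- stats::sd(d$onset)
  }
  d
}

build_formula <- function(spec, terms = spec$fixed) {
  rhs <- paste(c(if (length(terms)) terms else "1",
                 if (!is.null(spec$offset)) {
                   sprintf("offset(%s)", spec$offset)
                 },
                 spec$random),
               collapse = " + ")
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit one model family by maximum likelihood
#'
#' Gaussian families are fitted with `lme4::lmer` (ML, not REML, so that
#' likelihood-ratio comparisons are valid), the Poisson family with
#' `lme4::glmer` (log link, log phonation-time offset), and the beta family
#' with `glmmTMB::glmmTMB` (logit link, fixed precision). Convergence
#' problems and singular fits are recorded on the result, never silently
#' dropped.
#'
#' @param data Output of [prepare_covariates()].
#' @param spec A [model_spec()].
#' @param terms Fixed-effect terms to fit (default the full specification;
#'   pass `null_model_terms(spec)` for the null model).
#' @param control Optional `lme4::lmerControl()` / `lme4::glmerControl()`
#'   object. The default uses the bobyqa optimizer without the (expensive)
#'   finite-difference derivative check; convergence is still tracked via
#'   the optimizer's own return code.
#' @param start Optional starting values passed to the fitter (for warm
#'   starts in refit-heavy workflows).
#' @return An object of class `regspeech_fit`: list with `fit` (the fitted
#'   model object), `spec`, `terms`, `logLik`, `df`, `estimates` (tibble of
#'   fixed effects and standard errors), `converged`, `singular`,
#'   `messages`.
#' @export
fit_model <- function(data, spec, terms = spec$fixed, control = NULL,
                      start = NULL) {
  # design factors with a single observed level cannot enter the model
  # matrix; drop the terms that involve them (with a message)
  comp <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  degenerate <- comp[vapply(comp, function(cc) {
    v <- data[[cc]]
    !is.null(v) && is.factor(v) && length(unique(as.character(v))) < 2L
  }, logical(1))]
  if (length(degenerate)) {
    keep <- !vapply(strsplit(terms, ":", fixed = TRUE),
                    function(p) any(p %in% degenerate), logical(1))
    message("dropping term(s) with single-level factor(s) ",
            paste(degenerate, collapse = ", "), ": ",
            paste(terms[!keep], collapse = ", "))
    terms <- terms[keep]
  }
  fml <- build_formula(spec, terms)
  msgs <- character(0)
  collect <- function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  # do.call records evaluated arguments in the call, so downstream refits
  # (bootMer, update) do not depend on this function's environment
  fit <- withCallingHandlers(
    switch(spec$error_family,
      gaussian = suppressMessages(do.call(lme4::lmer, c(list(
        formula = fml, data = data, REML = FALSE,
        control = control %||% lme4::lmerControl(optimizer = "bobyqa",
                                                 calc.derivs = FALSE)),
        if (!is.null(start)) list(start = start)))),
      poisson = suppressMessages(do.call(lme4::glmer, c(list(
        formula = fml, data = data, family = stats::poisson(),
        control = control %||% lme4::glmerControl(optimizer = "bobyqa",
                                                  calc.derivs = FALSE)),
        if (!is.null(start)) list(start = start)))),
      beta = do.call(glmmTMB::glmmTMB, list(
        formula = fml, data = data, family = glmmTMB::beta_family()))
    ),
    warning = collect
  )
  if (spec$error_family == "beta") {
    est <- glmmTMB::fixef(fit)$cond
    se <- sqrt(diag(stats::vcov(fit)$cond))
    singular <- FALSE
    converged <- isTRUE(fit$sdr$pdHess)
  } else {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    singular <- lme4::isSingular(fit)
    # a singular fit (zero variance component) is reported via `singular`,
    # not treated as a convergence failure
    conv_msgs <- grep("singular", unlist(fit@optinfo$conv$lme4$messages),
                      value = TRUE, invert = TRUE)
    converged <- isTRUE(fit@optinfo$conv$opt == 0) && length(conv_msgs) == 0L
  }
  ll <- stats::logLik(fit)
  structure(
    list(fit = fit, spec = spec, terms = terms,
         logLik = as.numeric(ll), df = attr(ll, "df"),
         estimates = tibble::tibble(term = names(est),
                                    estimate = unname(est),
                                    se = unname(se)),
         converged = converged, singular = singular,
         messages = unique(c(msgs,
                             if (spec$error_family != "beta") {
                               unlist(fit@optinfo$conv$lme4$messages)
                             }))),
    class = "regspeech_fit"
  )
}

#' @exportS3Method base::print
print.regspeech_fit <- function(x, ...) {
  cat(sprintf("<%s model (family %d, %s): logLik %.1f on %d df%s%s>\n",
              x$spec$error_family, x$spec$family_id, x$spec$measure,
              x$logLik, x$df,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$singular) ", singular fit" else ""))
  print(x$estimates)
  invisible(x)
}

#' Fixed-effect terms of the null model
#'
#' The null specification removes register and every interaction containing
#' register, leaving the rest of the model (including its random structure)
#' unchanged.
#'
#' @param spec A [model_spec()].
#' @return Character vector of fixed terms.
#' @export
null_model_terms <- function(spec) {
  null_terms(spec$fixed)
}

#' Full-null likelihood-ratio comparison
#'
#' Tests the overall contribution of register (main effect plus all its
#' interactions) with one likelihood-ratio test, avoiding cryptic multiple
#' testing across the individual register terms. A negative statistic is a
#' convergence symptom and is flagged, not silently truncated.
#'
#' @param full,null `regspeech_fit` objects on the same data, null nested in
#'   full.
#' @return A list with `statistic`, `df`, `p_value`, `converged`.
#' @export
full_null_comparison <- function(full, null) {
  stat <- 2 * (full$logLik - null$logLik)
  df <- full$df - null$df
  if (df <= 0) {
    stop_config("null model is not nested in the full model (df difference %d)",
                df)
  }
  converged <- stat >= 0 && full$converged && null$converged
  list(statistic = stat, df = df,
       p_value = stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE),
       converged = converged)
}

# Drop-one likelihood-ratio p-value for a single fixed term, against an
# already fitted current model.
drop_one_p <- function(data, spec, current, term) {
  red <- fit_model(data, spec, setdiff(current$terms, term))
  stat <- 2 * (current$logLik - red$logLik)
  df <- current$df - red$df
  stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

#' Iteratively prune non-significant interactions
#'
#' Starting from the full model, repeatedly tests the currently droppable
#' interactions (those not contained in a retained higher-order term) with
#' drop-one likelihood-ratio tests, removing simultaneously all
#' non-significant (`p > alpha`) interactions of the same and highest
#' order, then refits; stops when every remaining interaction is
#' significant. Main effects are never removed. Intended to run after a
#' significant full-null comparison.
#'
#' @param data Output of [prepare_covariates()].
#' @param spec A [model_spec()].
#' @param alpha Retention threshold (default 0.1).
#' @return A list with `fit` (the reduced `regspeech_fit`) and `trace`
#'   (tibble of steps: term, order, p-value, removed).
#' @export
prune_interactions <- function(data, spec, alpha = 0.1) {
  terms <- spec$fixed
  trace <- list()
  step <- 0L
  repeat {
    ints <- terms[term_order(terms) > 1]
    droppable <- ints[!vapply(ints, function(a) {
      any(vapply(ints, function(b) term_contained_in(a, b), logical(1)))
    }, logical(1))]
    if (!length(droppable)) break
    current <- fit_model(data, spec, terms)
    removed_any <- FALSE
    for (o in sort(unique(term_order(droppable)), decreasing = TRUE)) {
      cand <- order_terms(droppable[term_order(droppable) == o])
      ps <- vapply(cand, function(tm) drop_one_p(data, spec, current, tm),
                   numeric(1))
      remove <- cand[ps > alpha]
      step <- step + 1L
      trace[[step]] <- tibble::tibble(step = step, term = cand, order = o,
                                      p_value = unname(ps),
                                      removed = cand %in% remove)
      if (length(remove)) {
        terms <- setdiff(terms, remove)
        removed_any <- TRUE
        break
      }
    }
    if (!removed_any) break
  }
  list(fit = fit_model(data, spec, terms),
       trace = if (length(trace)) dplyr::bind_rows(trace) else
         tibble::tibble(step = integer(0), term = character(0),
                        order = integer(0), p_value = numeric(0),
                        removed = logical(0)))
}

#' Parametric-bootstrap confidence intervals for the fixed effects
#'
#' Simulates responses from the fitted model, refits, and returns percentile
#' intervals of the fixed-effect estimates. Seeded and reproducible. If more
#' than 10% of refits fail, a warning is attached to the result.
#'
#' @param fitted A `regspeech_fit`.
#' @param n Number of bootstrap replicates (> 0).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Tibble with `term`, `estimate`, `lower`, `upper`, plus attributes
#'   `n_fail` and possibly a warning.
#' @export
bootstrap_ci <- function(fitted, n = 1000, seed = 1, level = 0.95) {
  if (!is_count(n)) stop_config("n must be a positive integer")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  with_seed(seed, {
    if (fitted$spec$error_family == "beta") {
      sims <- stats::simulate(fitted$fit, nsim = n)
      draws <- matrix(NA_real_, nrow = n, ncol = nrow(fitted$estimates))
      for (i in seq_len(n)) {
        d <- fitted$fit$frame
        d$response <- sims[[i]]
        r <- tryCatch(glmmTMB::fixef(stats::update(fitted$fit, data = d))$cond,
                      error = function(e) NULL)
        if (!is.null(r)) draws[i, ] <- r
      }
    } else {
      bt <- suppressWarnings(
        lme4::bootMer(fitted$fit, FUN = lme4::fixef, nsim = n,
                      type = "parametric"))
      draws <- bt$t
    }
    ok <- stats::complete.cases(draws)
    out <- tibble::tibble(
      term = fitted$estimates$term,
      estimate = fitted$estimates$estimate,
      lower = apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                    probs = probs[1]),
      upper = apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                    probs = probs[2])
    )
    attr(out, "n_fail") <- sum(!ok)
    if (sum(!ok) > 0.1 * n) {
      warning(sprintf("%d of %d bootstrap refits failed", sum(!ok), n),
              call. = FALSE)
    }
    out
  })
}

#' Leave-one-level-out stability of the fixed effects
#'
#' Refits the model excluding each level of a grouping factor in turn and
#' reports the range of every fixed-effect estimate across the refits;
#' tight ranges indicate that no single child/parent drives the estimates.
#'
#' @param data Output of [prepare_covariates()].
#' @param spec A [model_spec()].
#' @param grouping Column name of the grouping factor (>= 3 levels).
#' @return Tibble with `term`, `estimate` (full data), `min`, `max`;
#'   attribute `failed_levels` lists levels whose refit did not produce
#'   estimates.
#' @export
stability_leave_one_out <- function(data, spec, grouping = "family_id") {
  levels <- unique(data[[grouping]])
  if (length(levels) < 3L) {
    stop_config("grouping '%s' has fewer than 3 levels", grouping)
  }
  full <- fit_model(data, spec)
  ests <- list()
  failed <- character(0)
  for (lv in levels) {
    r <- tryCatch(
      fit_model(data[data[[grouping]] != lv, , drop = FALSE], spec)$estimates,
      error = function(e) NULL)
    if (is.null(r)) failed <- c(failed, as.character(lv)) else
      ests[[as.character(lv)]] <- r$estimate
  }
  m <- do.call(cbind, ests)
  out <- tibble::tibble(
    term = full$estimates$term,
    estimate = full$estimates$estimate,
    min = apply(m, 1, min),
    max = apply(m, 1, max)
  )
  attr(out, "failed_levels") <- failed
  out
}
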