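#' Response transforms
#'
#' The movement models use two variance-stabilising transforms:
#' arcsine-square-root for proportion responses (attendance as a fraction in
#' \[0, 1\] — divide percentages by 100 first) and the natural logarithm for
#' multiplicative positive responses (durations, distances, perch times).
#'
#' @param x Numeric vector.
#' @param kind `"none"`, `"log"` or `"arcsine_sqrt"`.
#' @return Transformed (or back-transformed) vector.
#' @export
transform_response <- function(x, kind = c("none", "log", "arcsine_sqrt")) {
  kind <- match.arg(kind)
  switch(kind,
    none = x,
    log = {
      if (any(x <= 0, na.rm = TRUE)) {
        stop("log transform requires strictly positive values", call. = FALSE)
      }
      log(x)
    },
    arcsine_sqrt = {
      if (any(x < 0 | x > 1, na.rm = TRUE)) {
        stop("arcsine_sqrt requires values in [0, 1] ",
             "(divide percentages by 100)", call. = FALSE)
      }
      asin(sqrt(x))
    }
  )
}

#' @rdname transform_response
#' @export
inverse_transform <- function(x, kind = c("none", "log", "arcsine_sqrt")) {
  kind <- match.arg(kind)
  switch(kind,
    none = x,
    log = exp(x),
    arcsine_sqrt = sin(x)^2
  )
}

#' Akaike weights
#'
#' Normalised relative model likelihoods: with `d_i = AIC_i - min(AIC)`,
#' `w_i = exp(-d_i / 2) / sum_j exp(-d_j / 2)`.
#'
#' @param aic Numeric vector of AIC values.
#' @return Weights summing to 1, in the input order.
#' @export
aic_weights <- function(aic) {
  stopifnot(length(aic) >= 1, all(is.finite(aic)))
  rel <- exp(-(aic - min(aic)) / 2)
  rel / sum(rel)
}

#' Holm step-down adjustment
#'
#' Familywise-error control for a set of simultaneous tests; adjusted
#' p-values are always at least the raw ones and monotone in the raw order.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted p-values, order preserved.
#' @export
holm_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "holm")
}

#' Fit one mixed model of the comparison framework
#'
#' Thin declarative wrapper around lme4: builds the model formula from a
#' response (with optional transform), fixed-effect terms and random
#' intercepts, and fits with the requested family/link (gaussian/identity
#' via `lmer`, poisson/log or binomial/logit via `glmer`). Estimation is
#' maximum likelihood (`method = "ML"`) for likelihood-ratio comparisons
#' and REML (`method = "REML"`, gaussian only) for reported coefficients.
#' Random factors with fewer than two levels in the data are dropped with a
#' warning. Non-convergence is flagged on the result, never silent.
#'
#' @param data Model frame.
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect terms (formula syntax,
#'   e.g. `c("sex * period", "sampling_frequency")`).
#' @param family `"gaussian"`, `"poisson"` or `"binomial"`.
#' @param random Character vector of random-intercept grouping columns.
#' @param transform Response transform (see [transform_response()]).
#' @param method `"ML"` or `"REML"`.
#' @return A `cpf_fit` object: the lme4 model plus spec, logLik, AIC and a
#'   tidy coefficient table with back-transformed estimates where the
#'   transform/link admits one.
#' @export
fit_mixed <- function(data, response, fixed = "1",
                      family = c("gaussian", "poisson", "binomial"),
                      random = c("individual_id", "year", "colony"),
                      transform = "none", method = c("ML", "REML")) {
  family <- match.arg(family)
  method <- match.arg(method)
  data <- as.data.frame(data)
  data$.y <- transform_response(data[[response]], transform)
  random <- random[random %in% names(data)]
  usable <- vapply(random, function(r) length(unique(data[[r]])) >= 2,
                   logical(1))
  if (any(!usable)) {
    warning("random factor(s) dropped (fewer than 2 levels): ",
            paste(random[!usable], collapse = ", "), call. = FALSE)
  }
  random <- random[usable]
  if (!length(random)) {
    stop("no usable random factors; a mixed model needs at least one",
         call. = FALSE)
  }
  rhs <- paste(c(fixed, paste0("(1 | ", random, ")")), collapse = " + ")
  form <- as.formula(paste(".y ~", rhs))
  model <- if (family == "gaussian") {
    lme4::lmer(form, data = data, REML = (method == "REML"))
  } else {
    lme4::glmer(form, data = data,
                family = if (family == "poisson") stats::poisson("log")
                         else stats::binomial("logit"))
  }
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  structure(list(
    model = model, data = data, response = response, fixed = fixed,
    family = family, random = random, transform = transform,
    method = method, converged = converged,
    logLik = as.numeric(logLik(model)), AIC = AIC(model),
    coefficients = tidy_coefs(model, transform, family)
  ), class = "cpf_fit")
}

tidy_coefs <- function(model, transform, family) {
  b <- if (inherits(model, "merMod")) lme4::fixef(model) else coef(model)
  se <- sqrt(diag(as.matrix(vcov(model))))
  out <- tibble::tibble(term = names(b), estimate = unname(b),
                        std_error = unname(se))
  # Back-transformed view: exp() under a log transform or log link,
  # sin^2 under arcsine-sqrt, inverse-logit for binomial. Only the scale
  # the estimate lives on admits a pointwise inverse.
  inv <- if (transform == "log" || family == "poisson") {
    exp
  } else if (transform == "arcsine_sqrt") {
    function(x) sin(pmax(pmin(x, pi / 2), 0))^2
  } else if (family == "binomial") {
    plogis
  } else {
    identity
  }
  out$back_transformed <- inv(out$estimate)
  out
}

#' @export
print.cpf_fit <- function(x, ...) {
  cat("<cpf_fit> ", x$family, " mixed model (", x$method, ")\n", sep = "")
  cat("  response: ", x$response,
      if (x$transform != "none") paste0(" [", x$transform, "]"), "\n",
      sep = "")
  cat("  fixed:    ", paste(x$fixed, collapse = " + "), "\n", sep = "")
  cat("  random:   ", paste(x$random, collapse = ", "), "\n", sep = "")
  cat("  AIC: ", round(x$AIC, 2),
      if (!x$converged) "  [DID NOT CONVERGE]", "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test for one fixed-effect term
#'
#' Refits the model without the term (both fits by maximum likelihood) and
#' compares by LRT; the degrees of freedom are the parameter-count
#' difference.
#'
#' @param fit A `cpf_fit` fitted with `method = "ML"`.
#' @param term A term label present in the model (e.g. `"sex:period"`).
#' @return One-row tibble: term, chisq, df, p_value.
#' @export
lrt_term <- function(fit, term) {
  full_terms <- attr(stats::terms(as.formula(
    paste("~", paste(fit$fixed, collapse = "+")))), "term.labels")
  if (!term %in% full_terms) {
    stop("term not in model: ", term, call. = FALSE)
  }
  reduced_terms <- setdiff(full_terms, term)
  # fit$data already carries the transformed response as .y; refit on .y
  # with no further transform so full and reduced models see one scale.
  red <- fit_mixed(fit$data, ".y",
                   fixed = if (length(reduced_terms)) reduced_terms else "1",
                   family = fit$family, random = fit$random,
                   transform = "none", method = "ML")
  an <- anova(red$model, fit$model)
  tibble::tibble(term = term,
                 chisq = an$Chisq[2], df = an$Df[2],
                 p_value = an$`Pr(>Chisq)`[2])
}

#' Backward-stepwise term elimination by LRT
#'
#' Starting from the full model, repeatedly drops the least significant
#' droppable term (LRT p >= alpha), respecting marginality (main effects
#' are kept while an interaction containing them stands) and never dropping
#' the correction factor. Stops when every remaining droppable term has
#' p < alpha.
#'
#' @inheritParams fit_mixed
#' @param alpha Retention threshold (default 0.05).
#' @param keep Terms never dropped (e.g. the GPS sampling-frequency
#'   correction factor).
#' @return List with the final `cpf_fit` (ML), the final term set, and a
#'   `trail` tibble recording every tested term at every step.
#' @export
backward_stepwise <- function(data, response, fixed,
                              family = "gaussian",
                              random = c("individual_id", "year", "colony"),
                              transform = "none", alpha = 0.05,
                              keep = character()) {
  terms_now <- attr(stats::terms(as.formula(
    paste("~", paste(fixed, collapse = "+")))), "term.labels")
  data <- as.data.frame(data)
  data$.y <- transform_response(data[[response]], transform)
  trail <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    fit <- fit_mixed(data, ".y",
                     fixed = if (length(terms_now)) terms_now else "1",
                     family = family, random = random,
                     transform = "none", method = "ML")
    droppable <- droppable_terms(terms_now, keep)
    if (!length(droppable)) break
    tests <- dplyr::bind_rows(lapply(droppable, function(tm) lrt_term(fit, tm)))
    tests$step <- step
    worst <- which.max(tests$p_value)
    if (tests$p_value[worst] >= alpha) {
      tests$action <- ifelse(seq_len(nrow(tests)) == worst, "dropped", "kept")
      terms_now <- setdiff(terms_now, tests$term[worst])
      trail[[step]] <- tests
    } else {
      tests$action <- "kept"
      trail[[step]] <- tests
      break
    }
  }
  final <- fit_mixed(data, ".y",
                     fixed = if (length(terms_now)) terms_now else "1",
                     family = family, random = random,
                     transform = "none", method = "ML")
  list(fit = final, terms = terms_now,
       trail = dplyr::bind_rows(trail))
}

# Terms that can be dropped: not protected, and not a main effect (or
# lower-order interaction) nested inside a surviving higher-order term.
droppable_terms <- function(terms_now, keep) {
  if (!length(terms_now)) return(character())
  parts <- strsplit(terms_now, ":", fixed = TRUE)
  droppable <- logical(length(terms_now))
  for (i in seq_along(terms_now)) {
    if (terms_now[i] %in% keep) next
    nested <- vapply(seq_along(terms_now), function(j) {
      j != i && all(parts[[i]] %in% parts[[j]])
    }, logical(1))
    droppable[i] <- !any(nested)
  }
  terms_now[droppable]
}

#' Fit a penalized-smooth (GAMM-style) model
#'
#' Gaussian additive mixed model with a penalized regression-spline smooth
#' of a continuous covariate (day of year in the body-mass analysis), the
#' smoothness selected by REML, optional parametric terms (e.g. sex) and
#' random intercepts as `bs = "re"` smooths.
#'
#' @param data Model frame.
#' @param response Response column name.
#' @param smooth_var Continuous covariate to smooth; `NULL` fits a purely
#'   parametric additive model (useful for AIC comparison against the
#'   smooth variants).
#' @param by Optional factor for separate smooths per level.
#' @param fixed Parametric fixed-effect terms (character, may be empty).
#' @param random Random-intercept grouping columns (factors).
#' @param k Basis dimension of the smooth (default 20): comfortably above
#'   the ~7-8 effective df a seasonal body-mass trend needs, so the REML
#'   penalty, not the basis ceiling, decides the fit.
#' @return A `cpf_smooth_fit`: mgcv fit, AIC, effective df of each smooth,
#'   and a tidy parametric coefficient table.
#' @export
fit_smooth <- function(data, response, smooth_var = "doy", by = NULL,
                       fixed = character(), random = "individual_id",
                       k = 20) {
  data <- as.data.frame(data)
  if (nrow(data) < 30) {
    stop("fit_smooth needs at least 30 observations spanning the season",
         call. = FALSE)
  }
  random <- random[random %in% names(data)]
  for (r in random) data[[r]] <- factor(data[[r]])
  if (!is.null(by)) data[[by]] <- factor(data[[by]])
  sm <- if (is.null(smooth_var)) {
    NULL
  } else if (is.null(by)) {
    sprintf("s(%s, k = %d)", smooth_var, k)
  } else {
    sprintf("s(%s, by = %s, k = %d)", smooth_var, by, k)
  }
  re <- if (length(random)) sprintf("s(%s, bs = \"re\")", random) else NULL
  rhs <- paste(c(sm, fixed, re), collapse = " + ")
  form <- as.formula(paste(response, "~", rhs))
  model <- mgcv::gam(form, data = data, method = "REML")
  s_tab <- summary(model)$s.table
  p_tab <- summary(model)$p.table
  structure(list(
    model = model, response = response, smooth_var = smooth_var,
    fixed = fixed, random = random,
    AIC = AIC(model), logLik = as.numeric(logLik(model)),
    edf = if (!is.null(s_tab)) s_tab[, "edf"] else numeric(0),
    coefficients = tibble::tibble(term = rownames(p_tab),
                                  estimate = p_tab[, 1],
                                  std_error = p_tab[, 2],
                                  p_value = p_tab[, 4])
  ), class = "cpf_smooth_fit")
}

#' @export
print.cpf_smooth_fit <- function(x, ...) {
  cat("<cpf_smooth_fit> gaussian additive mixed model (REML)\n")
  cat("  response:", x$response, "\n")
  cat("  smooth:  s(", x$smooth_var, "), edf = ",
      paste(round(x$edf, 2), collapse = ", "), "\n", sep = "")
  cat("  AIC:", round(x$AIC, 2), "\n")
  invisible(x)
}

#' Holm-corrected post-hoc contrasts for a sex x period interaction
#'
#' Two contrast families from one fitted interaction model: the sex
#' difference within each phenological period (4 tests) and all pairwise
#' period differences within each sex (2 x 6 tests). Wald z tests on the
#' model scale, Holm-adjusted — by default over the full 16-test family
#' (set `family = "within"` to correct each family separately). Period
#' comparisons within each sex are summarised as a compact letter display:
#' periods sharing a letter do not differ significantly.
#'
#' @param fit A `cpf_fit` whose fixed part contains `sex * period`.
#' @param family `"all"` (one Holm family) or `"within"`.
#' @param alpha Significance level for the letter display.
#' @return List: `contrasts` tibble (contrast, group, estimate, SE, z, raw
#'   and adjusted p) and `letters` tibble (sex, period, letter).
#' @export
posthoc_contrasts <- function(fit, family = c("all", "within"),
                              alpha = 0.05) {
  family <- match.arg(family)
  model <- fit$model
  em_sex <- emmeans::emmeans(model, ~ sex | period, data = fit$data)
  em_per <- emmeans::emmeans(model, ~ period | sex, data = fit$data)
  sex_tab <- as.data.frame(summary(emmeans::contrast(em_sex, "pairwise"),
                                   adjust = "none", infer = c(FALSE, TRUE)))
  per_tab <- as.data.frame(summary(emmeans::contrast(em_per, "pairwise"),
                                   adjust = "none", infer = c(FALSE, TRUE)))
  stat_col <- intersect(c("z.ratio", "t.ratio"), names(sex_tab))[1]
  mk <- function(tab, fam, group_col) {
    tibble::tibble(
      family = fam,
      contrast = as.character(tab$contrast),
      group = as.character(tab[[group_col]]),
      estimate = tab$estimate, std_error = tab$SE,
      statistic = tab[[stat_col]], p_raw = tab$p.value
    )
  }
  ct <- dplyr::bind_rows(mk(sex_tab, "sex_within_period", "period"),
                         mk(per_tab, "period_within_sex", "sex"))
  if (family == "all") {
    ct$p_adj <- holm_adjust(ct$p_raw)
  } else {
    ct <- ct |>
      dplyr::group_by(.data$family) |>
      dplyr::mutate(p_adj = holm_adjust(.data$p_raw)) |>
      dplyr::ungroup()
  }
  per_means <- as.data.frame(summary(em_per))
  letters <- dplyr::bind_rows(lapply(unique(per_means$sex), function(s) {
    sub <- ct[ct$family == "period_within_sex" & ct$group == s, ]
    means <- per_means[per_means$sex == s, ]
    lv <- as.character(means$period)
    tibble::tibble(
      sex = s, period = lv,
      letter = compact_letters(lv, sub$contrast, sub$p_adj < alpha,
                               order_by = means$emmean)
    )
  }))
  list(contrasts = ct, letters = letters)
}

#' Compact letter display
#'
#' Insert-and-absorb algorithm: groups not significantly different share at
#' least one letter; every significant pair shares none.
#'
#' @param groups Group labels.
#' @param contrasts Character vector `"a - b"` naming each pair.
#' @param significant Logical vector, one per contrast.
#' @param order_by Optional numeric used to order letter assignment
#'   (ascending); defaults to the input order.
#' @return Character vector of letter strings, one per group.
#' @export
compact_letters <- function(groups, contrasts, significant,
                            order_by = NULL) {
  ord <- if (is.null(order_by)) seq_along(groups) else order(order_by)
  g <- groups[ord]
  sets <- list(g)
  pairs <- strsplit(gsub("[()]", "", contrasts), " - ", fixed = TRUE)
  for (k in which(significant)) {
    a <- trimws(pairs[[k]][1]); b <- trimws(pairs[[k]][2])
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets fully contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[i] &&
            all(new_sets[[i]] %in% new_sets[[j]]) &&
            (length(new_sets[[i]]) < length(new_sets[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order sets by first member's position, assign letters
  first_pos <- vapply(sets, function(s) min(match(s, g)), numeric(1))
  sets <- sets[order(first_pos)]
  out <- vapply(groups, function(gr) {
    paste0(letters[which(vapply(sets, function(s) gr %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  unname(out)
}

#' Chi-squared homogeneity test for habitat-use counts
#'
#' Pearson chi-squared test of identical habitat-use distributions between
#' the sexes, on a 2 x k count table (df = k - 1).
#'
#' @param counts 2 x k matrix of non-negative counts; rows = sexes,
#'   columns = habitat classes. Column totals must be positive.
#' @return List: `statistic`, `df`, `p_value`, `expected`, and
#'   `low_expected` (TRUE when any expected count < 5, with a warning).
#' @export
chisq_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2 || any(counts < 0) ||
      any(colSums(counts) == 0) || any(rowSums(counts) == 0)) {
    stop("counts must be a 2 x k table of non-negative counts with ",
         "positive row and column totals", call. = FALSE)
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  low <- any(ht$expected < 5)
  if (low) {
    warning("some expected counts are below 5; the chi-squared ",
            "approximation may be poor", call. = FALSE)
  }
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected,
       low_expected = low)
}
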