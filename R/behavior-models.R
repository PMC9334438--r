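#' Specify a mixed model for the behavioral analyses
#'
#' @param response Response column name (binary 0/1 for binomial).
#' @param fixed Character vector of fixed-effect terms (interactions as
#'   \code{"a:b"}); empty for an intercept-only model.
#' @param random Character vector of random-intercept grouping columns.
#' @param family \code{"binomial"} (logit), \code{"gaussian"} (identity) or
#'   \code{"gaussian_log"} (Gaussian with log link).
#' @return List of class \code{"model_spec"}.
#' @export
model_spec <- function(response, fixed = character(),
                       random = c("dog_id", "control_speaker_id"),
                       family = c("binomial", "gaussian", "gaussian_log")) {
  family <- match.arg(family)
  structure(
    list(response = response, fixed = fixed, random = random, family = family),
    class = "model_spec"
  )
}

build_formula <- function(spec, random_keep) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  if (length(random_keep)) {
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", random_keep), collapse = " + "),
                 sep = " + ")
  }
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Odds ratio of a log-odds estimate
#'
#' @param estimate Log-odds scale estimate(s).
#' @return \code{exp(estimate)}.
#' @examples
#' odds_ratio(1.601)  # 4.957
#' @export
odds_ratio <- function(estimate) exp(estimate)

#' Fit a (generalized) linear mixed model for a behavioral analysis
#'
#' Wraps \pkg{lme4}/\pkg{lmerTest}: binomial models are fit by Laplace
#' maximum likelihood and report Wald z tests; Gaussian models use REML with
#' Satterthwaite degrees of freedom; Gaussian log-link models use penalized
#' iteratively reweighted least squares. Random factors with fewer than 2
#' levels in the data are dropped with a message (mirroring the omission of
#' a random factor that cannot explain variance); with no random factor
#' left, the corresponding fixed-effects model is fit.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param data Trial (or feature) table.
#' @return Object of class \code{"mixed_fit"}: list with \code{spec},
#'   \code{formula}, \code{fit} (the underlying model object),
#'   \code{coefficients} (term, estimate, se, stat, df, p and, for binomial
#'   models, odds_ratio), \code{ranef_var}, \code{logLik}.
#' @export
fit_mixed <- function(spec, data) {
  keep <- spec$random[vapply(spec$random, function(r) {
    !is.null(data[[r]]) && length(unique(data[[r]])) >= 2
  }, logical(1))]
  for (r in setdiff(spec$random, keep)) {
    message(sprintf("random factor '%s' has < 2 levels and is omitted", r))
  }
  fml <- build_formula(spec, keep)
  mixed <- length(keep) > 0
  fit <- switch(
    spec$family,
    binomial = if (mixed) {
      lme4::glmer(fml, data = data, family = stats::binomial())
    } else {
      stats::glm(fml, data = data, family = stats::binomial())
    },
    gaussian = if (mixed) {
      lmerTest::lmer(fml, data = data)
    } else {
      stats::lm(fml, data = data)
    },
    gaussian_log = if (mixed) {
      lme4::glmer(fml, data = data, family = stats::gaussian(link = "log"))
    } else {
      stats::glm(fml, data = data, family = stats::gaussian(link = "log"))
    }
  )
  co <- stats::coef(summary(fit))
  tab <- data.frame(
    term = rownames(co),
    estimate = co[, 1],
    se = co[, 2],
    stringsAsFactors = FALSE
  )
  if ("df" %in% colnames(co)) {
    tab$stat <- co[, "t value"]
    tab$df <- co[, "df"]
    tab$p <- co[, "Pr(>|t|)"]
  } else if ("z value" %in% colnames(co)) {
    tab$stat <- co[, "z value"]
    tab$df <- NA_real_
    tab$p <- co[, "Pr(>|z|)"]
  } else {
    tab$stat <- co[, "t value"]
    if ("Pr(>|t|)" %in% colnames(co)) {
      tab$df <- stats::df.residual(fit)
      tab$p <- co[, "Pr(>|t|)"]
    } else {
      # gaussian-log glmer reports t without df; Wald normal approximation
      tab$df <- NA_real_
      tab$p <- 2 * stats::pnorm(-abs(tab$stat))
    }
  }
  if (spec$family == "binomial") tab$odds_ratio <- odds_ratio(tab$estimate)
  rownames(tab) <- NULL
  rv <- if (mixed) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    stats::setNames(vc$vcov, ifelse(is.na(vc$grp), "residual", vc$grp))
  } else {
    c(residual = if (spec$family == "gaussian") stats::sigma(fit)^2 else NA_real_)
  }
  structure(
    list(spec = spec, formula = fml, fit = fit, coefficients = tab,
         ranef_var = rv, logLik = as.numeric(stats::logLik(fit))),
    class = "mixed_fit"
  )
}

#' @export
print.mixed_fit <- function(x, digits = 3, ...) {
  cat(deparse(x$formula), sprintf("[%s]\n", x$spec$family))
  tab <- x$coefficients
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

# terms still blocked from removal because a retained interaction contains them
blocked_terms <- function(fixed) {
  parts <- strsplit(fixed, ":", fixed = TRUE)
  inter <- fixed[lengths(parts) > 1]
  unique(unlist(strsplit(inter, ":", fixed = TRUE)))
}

# match a model_spec fixed term to coefficient-table rows: factors expand
# their levels into row names and R may reorder interaction components, so
# components are compared as sets with a prefix match per component
term_rows <- function(term, coef_terms) {
  idx <- which(coef_terms == term)
  if (length(idx)) return(idx)
  pieces <- strsplit(term, ":", fixed = TRUE)[[1]]
  hit <- vapply(coef_terms, function(ct) {
    cps <- strsplit(ct, ":", fixed = TRUE)[[1]]
    if (length(cps) != length(pieces)) return(FALSE)
    used <- logical(length(cps))
    for (p in pieces) {
      j <- which(!used & startsWith(cps, p))
      if (!length(j)) return(FALSE)
      used[j[1]] <- TRUE
    }
    all(used)
  }, logical(1))
  which(hit)
}

#' Backwards elimination of fixed effects
#'
#' Refits the model after removing, one at a time, the fixed term with the
#' largest p value at or above the stay threshold; interaction terms are
#' always eligible before the main effects they contain. The default
#' threshold 0.1 keeps terms associated with the response at least at the
#' tendency level.
#'
#' @param spec A \code{\link{model_spec}} (the full initial model).
#' @param data Trial table.
#' @param stay_p Stay threshold: terms with \code{p < stay_p} are retained.
#' @return The final \code{\link{fit_mixed}} object, with an
#'   \code{"elimination"} attribute logging each removal (term, p).
#' @export
backwards_eliminate <- function(spec, data, stay_p = 0.1) {
  log <- data.frame(step = integer(0), dropped = character(0), p = numeric(0))
  step <- 0L
  repeat {
    fit <- fit_mixed(spec, data)
    if (!length(spec$fixed)) break
    blocked <- blocked_terms(spec$fixed)
    elig <- setdiff(spec$fixed, blocked)
    if (!length(elig)) break
    coef_terms <- fit$coefficients$term
    pvals <- vapply(elig, function(tm) {
      rows <- term_rows(tm, coef_terms)
      if (!length(rows)) return(NA_real_)
      min(fit$coefficients$p[rows])  # a term stays if any level is associated
    }, numeric(1))
    worst <- which.max(pvals)
    if (!length(worst) || is.na(pvals[worst]) || pvals[worst] < stay_p) break
    step <- step + 1L
    log <- rbind(log, data.frame(step = step, dropped = elig[worst],
                                 p = pvals[worst]))
    spec$fixed <- setdiff(spec$fixed, elig[worst])
  }
  attr(fit, "elimination") <- log
  fit
}

#' Looking-time model with acoustic-distance covariates
#'
#' Fits the Gaussian mixed model of looking time with the six marker
#' distances (z-scored), gender match, and all distance-by-gender two-way
#' interactions in the initial model; applies backwards elimination; and,
#' when the f0-mean distance survives, computes the per-gender simple slopes
#' of f0 distance by recombining coefficients and their covariances
#' (Satterthwaite df via a 1-degree contrast).
#'
#' @param trials Trial table with \code{looking_time}, \code{gender_match},
#'   and \code{zdist_*} columns; rows flagged \code{distance_missing} are
#'   dropped with a message.
#' @param markers Marker names whose z-scored distances enter the model.
#' @param stay_p Stay threshold for elimination.
#' @return List with \code{fit} (final \code{\link{fit_mixed}}),
#'   \code{elimination} (log), and \code{simple_slopes} (data frame for
#'   same/different gender, or \code{NULL} when the f0 term was eliminated).
#' @export
looking_time_model <- function(trials,
                               markers = c("f0_mean", "f0_sd", "dF",
                                           "HNR", "ent", "ppj"),
                               stay_p = 0.1) {
  if (!is.null(trials$distance_missing) && any(trials$distance_missing)) {
    message(sprintf("dropping %d trials with missing distances",
                    sum(trials$distance_missing)))
    trials <- trials[!trials$distance_missing, , drop = FALSE]
  }
  trials$gender_match <- factor(trials$gender_match,
                                levels = c("same", "different"))
  dist_terms <- paste0("zdist_", intersect(markers, sub("^zdist_", "",
    grep("^zdist_", names(trials), value = TRUE))))
  if (!length(dist_terms)) stop("no z-scored distance columns found", call. = FALSE)
  fixed <- c("gender_match", dist_terms,
             paste0(dist_terms, ":gender_match"))
  spec <- model_spec("looking_time", fixed = fixed, random = "dog_id",
                     family = "gaussian")
  fit <- backwards_eliminate(spec, trials, stay_p = stay_p)

  slopes <- NULL
  ct <- fit$coefficients$term
  f0_row <- which(ct == "zdist_f0_mean")
  int_row <- grep("^zdist_f0_mean:gender_match|^gender_match.*:zdist_f0_mean",
                  ct)
  if (length(f0_row) && inherits(fit$fit, "lmerModLmerTest")) {
    nfx <- length(lme4::fixef(fit$fit))
    L_same <- numeric(nfx); L_same[f0_row] <- 1
    rows <- list(same = L_same)
    if (length(int_row)) {
      L_diff <- L_same; L_diff[int_row[1]] <- 1
      rows$different <- L_diff
    }
    slopes <- do.call(rbind, lapply(names(rows), function(nm) {
      cs <- lmerTest::contest1D(fit$fit, rows[[nm]])
      data.frame(gender = nm, estimate = cs$Estimate, se = cs$`Std. Error`,
                 df = cs$df, t = cs$`t value`, p = cs$`Pr(>|t|)`)
    }))
  }
  list(fit = fit, elimination = attr(fit, "elimination"),
       simple_slopes = slopes)
}

#' Wilcoxon signed-rank test for paired phase comparison
#'
#' Signed-rank test with zero differences dropped, average ranks for ties,
#' and the tie-corrected normal approximation. All-zero differences give
#' \code{Z = 0, p = 1} (no evidence of any phase difference).
#'
#' @param x,y Paired per-dog success proportions (e.g. test vs olfaction
#'   control phase).
#' @return List with \code{Z}, \code{p}, \code{W} (positive-rank sum) and
#'   \code{n_used} (pairs after dropping zeros).
#' @export
wilcoxon_phase_test <- function(x, y) {
  if (!length(x) || length(x) != length(y)) {
    stop("need paired vectors of equal positive length", call. = FALSE)
  }
  d <- x - y
  d <- d[!is.na(d)]
  if (!length(d)) stop("no complete pairs", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(Z = 0, p = 1, W = 0, n_used = 0L))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  Z <- if (sig2 > 0) (W - mu) / sqrt(sig2) else 0
  list(Z = Z, p = min(1, 2 * stats::pnorm(-abs(Z))), W = W, n_used = n)
}

#' Compare voices across speaker types with likelihood-ratio tests
#'
#' Tests whether mean f0 and jitter differ systematically between speaker
#' types (owners of included dogs, owners of excluded dogs, control
#' persons), with gender as a fixed factor and speaker identity as random
#' intercept. Mean f0 is modeled as Gaussian; jitter as Gaussian with log
#' link (it is positive and right-skewed). The speaker-type effect and the
#' type-by-gender interaction are each tested by likelihood ratio.
#'
#' @param features Per-sentence feature table with columns
#'   \code{speaker_id}, \code{speaker_type}, \code{gender}, \code{f0_mean},
#'   \code{ppj}.
#' @return Named list (\code{f0_mean}, \code{ppj}) of data frames with the
#'   LR chi-square, df and p for the type effect and interaction.
#' @export
speaker_voice_comparison <- function(features) {
  stopifnot(all(c("speaker_id", "speaker_type", "gender",
                  "f0_mean", "ppj") %in% names(features)))
  features <- features[stats::complete.cases(
    features[, c("f0_mean", "ppj")]), , drop = FALSE]
  features$speaker_type <- factor(features$speaker_type)
  features$gender <- factor(features$gender)
  if (nlevels(features$speaker_type) < 2) {
    stop("need at least 2 speaker types", call. = FALSE)
  }
  has_gender <- nlevels(features$gender) >= 2
  if (!has_gender) warning("single gender in input; gender term dropped")

  one <- function(resp, family) {
    base_fixed <- if (has_gender) "gender" else character(0)
    fit0 <- fit_mixed(model_spec(resp, base_fixed, "speaker_id", family),
                      features)
    fit1 <- fit_mixed(model_spec(resp, c(base_fixed, "speaker_type"),
                                 "speaker_id", family), features)
    lr_type <- lr_test(fit0, fit1)
    out <- data.frame(effect = "speaker_type", chisq = lr_type$chisq,
                      df = lr_type$df, p = lr_type$p)
    if (has_gender) {
      fit2 <- fit_mixed(model_spec(
        resp, c("gender", "speaker_type", "speaker_type:gender"),
        "speaker_id", family), features)
      lr_int <- lr_test(fit1, fit2)
      out <- rbind(out, data.frame(effect = "speaker_type:gender",
                                   chisq = lr_int$chisq, df = lr_int$df,
                                   p = lr_int$p))
    }
    out
  }
  list(
    f0_mean = one("f0_mean", "gaussian"),
    ppj = one("ppj", "gaussian_log")
  )
}

# likelihood-ratio test between two nested mixed_fit objects (ML refit for
# REML Gaussian fits)
lr_test <- function(small, large) {
  ll <- function(mf) {
    f <- mf$fit
    if (inherits(f, "lmerMod") && lme4::isREML(f)) {
      f <- lme4::refitML(f)
    }
    list(ll = as.numeric(stats::logLik(f)),
         df = attr(stats::logLik(f), "df"))
  }
  a <- ll(small); b <- ll(large)
  chisq <- max(0, 2 * (b$ll - a$ll))
  df <- max(1L, b$df - a$df)
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}
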