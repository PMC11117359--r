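#' Screen predictors for collinearity
#'
#' Greedy removal of collinear predictors based on pairwise Spearman rank
#' correlations: while any retained pair has `|rho| >= threshold`, the pair
#' with the largest `|rho|` is resolved by dropping one of its members. A
#' predictor named in `drop_preference` is dropped first (this is where an
#' ecological preference, e.g. discarding a redundant infrastructure
#' variable, is expressed); otherwise the member with the larger mean
#' absolute correlation to all other retained predictors goes, with an
#' alphabetical tie-break.
#'
#' @param data Tibble containing the predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param threshold Absolute Spearman correlation above which a pair is
#'   considered collinear (default 0.7; retained pairs satisfy
#'   `|rho| < threshold`).
#' @param drop_preference Character vector of predictors to drop
#'   preferentially when involved in a collinear pair.
#' @return List of class `predictor_screen` with `retained` (character) and
#'   `dropped` (tibble: `predictor`, `correlated_with`, `rho`).
#' @export
screen_collinearity <- function(data, predictors, threshold = 0.7,
                                drop_preference = NULL) {
  stopifnot(length(predictors) >= 2, nrow(data) >= 3)
  x <- as.data.frame(data[predictors])
  constant <- vapply(x, function(v) sd(v) == 0 || all(is.na(v)), logical(1))
  if (any(constant)) {
    warn(paste0("constant predictor(s) have undefined rank correlation: ",
                paste(predictors[constant], collapse = ", ")))
  }
  rho <- suppressWarnings(cor(x, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 0
  retained <- predictors
  dropped <- tibble::tibble(predictor = character(), correlated_with = character(),
                            rho = numeric())
  repeat {
    r <- abs(rho[retained, retained, drop = FALSE])
    r[is.na(r)] <- 0
    if (max(r) < threshold) break
    idx <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- sort(c(retained[idx[1]], retained[idx[2]]))
    pref <- intersect(drop_preference, pair)
    victim <- if (length(pref)) pref[1] else {
      means <- rowMeans(r[pair, , drop = FALSE])
      pair[order(-means, pair)][1]
    }
    other <- setdiff(pair, victim)
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      predictor = victim, correlated_with = other,
      rho = rho[victim, other]))
    retained <- setdiff(retained, victim)
  }
  structure(list(retained = retained, dropped = dropped, threshold = threshold),
            class = "predictor_screen")
}

#' @export
print.predictor_screen <- function(x, ...) {
  cat("Predictor screen (|Spearman rho| <", x$threshold, "retained)\n")
  cat("Retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) {
    cat("Dropped:\n")
    print(x$dropped)
  } else cat("Dropped: none\n")
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`. For Gaussian fits the
#' log-likelihood must use the ML variance estimate and `k` must count the
#' residual variance as a parameter for AICc values to be comparable.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters (coefficients + intercept +
#'   residual variance).
#' @param n Sample size; `n - k - 1` must be positive, otherwise `Inf` is
#'   returned (the model cannot be ranked).
#' @return The AICc value.
#' @export
#' @examples
#' aicc(0, k = 2, n = 26)  # 4 + 12/23
aicc <- function(loglik, k, n) {
  ifelse(n - k - 1 > 0, -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1), Inf)
}

#' Fit all predictor subsets as Gaussian GLMs
#'
#' Fits one ordinary-least-squares (Gaussian ML) model per subset of the
#' predictors, including the intercept-only model — `2^p` candidates in all,
#' with no interactions. Each fit records its coefficients, standard
#' errors, ML log-likelihood, parameter count `k` (intercept + slopes +
#' residual variance), AICc, and plain and adjusted R-squared.
#'
#' @param data Tibble with the response and predictor columns.
#' @param response Name of the response column (e.g. per-site RAI1).
#' @param predictors Character vector of predictor names (already screened
#'   for collinearity).
#' @return Tibble with one row per fitted subset; list-columns `terms`
#'   (character vector of included predictors), `coef` and `se` (named
#'   numeric vectors including the intercept).
#' @export
fit_all_subsets <- function(data, response, predictors) {
  n <- nrow(data)
  y <- data[[response]]
  if (any(!is.finite(y))) abort("response contains non-finite values")
  subsets <- unlist(lapply(0:length(predictors), function(m) {
    if (m == 0) return(list(character(0)))
    apply(combn(predictors, m), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
  rows <- purrr::map(subsets, function(terms) {
    f <- if (length(terms)) {
      stats::reformulate(terms, response = response)
    } else {
      stats::as.formula(paste(response, "~ 1"))
    }
    fit <- lm(f, data = data)
    if (any(is.na(coef(fit)))) {
      warn(paste0("singular design for subset {", paste(terms, collapse = ", "),
                  "}; skipped"))
      return(NULL)
    }
    k <- length(coef(fit)) + 1  # + residual variance
    ll <- as.numeric(logLik(fit))  # ML variance estimate
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - rss / tss else NA_real_
    p <- length(terms)
    adj <- if (p == 0) 0 else 1 - (1 - r2) * (n - 1) / (n - p - 1)
    tibble::tibble(
      model = paste(if (length(terms)) terms else "(intercept)", collapse = "+"),
      terms = list(terms),
      coef = list(coef(fit)),
      se = list(sqrt(diag(vcov(fit)))),
      loglik = ll, k = k, n_obs = n,
      aicc = aicc(ll, k, n),
      r2 = r2, adj_r2 = adj
    )
  })
  dplyr::bind_rows(rows)
}

#' Rank candidate models by AICc
#'
#' Adds AICc differences and Akaike weights to a candidate model table:
#' `delta_aicc = AICc - min(AICc)` and
#' `weight = exp(-delta/2) / sum(exp(-delta/2))`. Models with
#' `delta_aicc < 2` form the best-supported set.
#'
#' @param models Tibble from [fit_all_subsets()] (needs an `aicc` column).
#' @return The table sorted by AICc with `delta_aicc`, `weight` and logical
#'   `best_set` columns.
#' @export
rank_and_weight <- function(models) {
  stopifnot(nrow(models) >= 1)
  models |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc),
                  weight = exp(-.data$delta_aicc / 2) /
                    sum(exp(-.data$delta_aicc / 2)),
                  best_set = .data$delta_aicc < 2) |>
    dplyr::arrange(.data$delta_aicc)
}

#' Multimodel-inference summary per predictor
#'
#' For each predictor: its selection probability (the summed Akaike weights
#' of all models containing it), the conditional model-averaged coefficient
#' (weights renormalised over the containing models), and the unconditional
#' standard error combining within-model sampling variance and between-model
#' coefficient spread:
#' `SE = sqrt( sum w'_i (se_i^2 + (b_i - b_bar)^2) )`.
#'
#' @param models Ranked model table from [rank_and_weight()].
#' @param predictors Predictors to summarise (default: all appearing in any
#'   model).
#' @return Tibble `predictor, selection_probability, coefficient, se`; a
#'   predictor in no model has probability 0 and `NA` coefficient.
#' @export
mmi_summary <- function(models, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- unique(unlist(models$terms))
  }
  purrr::map_dfr(predictors, function(p) {
    has <- purrr::map_lgl(models$terms, ~ p %in% .x)
    prob <- sum(models$weight[has])
    if (!any(has)) {
      return(tibble::tibble(predictor = p, selection_probability = 0,
                            coefficient = NA_real_, se = NA_real_))
    }
    w <- models$weight[has] / sum(models$weight[has])
    b <- purrr::map_dbl(models$coef[has], ~ .x[[p]])
    s <- purrr::map_dbl(models$se[has], ~ .x[[p]])
    bbar <- sum(w * b)
    tibble::tibble(predictor = p, selection_probability = prob,
                   coefficient = bbar,
                   se = sqrt(sum(w * (s^2 + (b - bbar)^2))))
  })
}

#' Adjusted R-squared
#'
#' `1 - (1 - R^2) (n - 1) / (n - k - 1)` with `k` the number of slope terms.
#'
#' @param r2 Plain R-squared.
#' @param n Number of observations.
#' @param k Number of predictors (slopes, excluding intercept).
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, k) {
  stopifnot(n > k + 1)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Habitat-suitability multimodel inference
#'
#' End-to-end wrapper: screens predictors for collinearity, fits all
#' subsets as Gaussian GLMs of the (per-site) activity index, ranks them by
#' AICc, and summarises predictor support. Mirrors the standard
#' information-theoretic workflow for small camera-trap samples.
#'
#' @inheritParams fit_all_subsets
#' @inheritParams screen_collinearity
#' @param screen If `TRUE` (default), apply [screen_collinearity()] first.
#' @return Object of class `habitat_mmi` with elements `models` (ranked
#'   table), `summary` (per-predictor), `screen`, `response`, `n`.
#'   [tidy()] returns the per-predictor summary, [glance()] the best-model
#'   statistics.
#' @export
habitat_mmi <- function(data, response, predictors, threshold = 0.7,
                        drop_preference = NULL, screen = TRUE) {
  scr <- if (screen) {
    screen_collinearity(data, predictors, threshold, drop_preference)
  } else {
    structure(list(retained = predictors,
                   dropped = tibble::tibble(predictor = character(),
                                            correlated_with = character(),
                                            rho = numeric()),
                   threshold = threshold), class = "predictor_screen")
  }
  models <- fit_all_subsets(data, response, scr$retained) |> rank_and_weight()
  structure(list(models = models,
                 summary = mmi_summary(models, scr$retained),
                 screen = scr, response = response, n = nrow(data)),
            class = "habitat_mmi")
}

#' @rdname habitat_mmi
#' @param x A `habitat_mmi` object.
#' @param ... Unused.
#' @export
tidy.habitat_mmi <- function(x, ...) x$summary

#' @rdname habitat_mmi
#' @export
glance.habitat_mmi <- function(x, ...) {
  best <- x$models[1, ]
  tibble::tibble(n_models = nrow(x$models), n_best_set = sum(x$models$best_set),
                 best_model = best$model, best_aicc = best$aicc,
                 best_weight = best$weight, best_r2 = best$r2,
                 best_adj_r2 = best$adj_r2, n_obs = x$n)
}

#' @rdname habitat_mmi
#' @export
print.habitat_mmi <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Habitat MMI (%d models on %d sites)\n", g$n_models, g$n_obs))
  cat(sprintf("Best model: %s (AICc %.2f, wt %.2f, adj R2 %.2f); %d model(s) with dAICc < 2\n",
              g$best_model, g$best_aicc, g$best_weight, g$best_adj_r2, g$n_best_set))
  print(x$summary)
  invisible(x)
}

#' @rdname habitat_mmi
#' @param object A `habitat_mmi` object.
#' @export
autoplot.habitat_mmi <- function(object, ...) {
  d <- dplyr::arrange(object$summary, .data$selection_probability)
  d$predictor <- factor(d$predictor, levels = d$predictor)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$selection_probability, y = .data$predictor)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "Selection probability", y = NULL,
                  title = paste("Predictor support for", object$response)) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}
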