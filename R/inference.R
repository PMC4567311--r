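#' Fit a linear mixed model for log defoliation
#'
#' Fits `log(response) ~ fixed terms + (1 | plot_id)` with lme4. The log
#' transform stabilises the variance of the strictly positive defoliation
#' proportions; slopes are invariant to the response's scale (percent vs
#' proportion). A singular fit (plot variance estimated at zero) is
#' returned with a flag, not an error.
#'
#' @param data data.frame with the response, the fixed-effect columns and
#'   `plot_id`.
#' @param terms Character vector of fixed-effect terms (may include `:`
#'   interactions); `character(0)` gives the intercept-only null model.
#' @param response Response column name (default `"td"`); must be
#'   positive.
#' @param method `"REML"` (default; reported estimates/SE/t) or `"ML"`
#'   (likelihoods comparable across fixed structures, used for AICc).
#' @param log_response Apply the natural-log transform (default TRUE).
#' @param group Random-intercept grouping column (default `"plot_id"`).
#' @return List of class `lmm_fit`: `model` (the merMod), `terms`,
#'   `method`, `n`, `K` (estimable parameters: fixed effects + residual
#'   and plot variances), `logLik`, `coefficients` (data.frame term,
#'   estimate, se, t, p with residual-df p-values), `singular`.
#' @export
fit_lmm <- function(data, terms = character(0), response = "td",
                    method = c("REML", "ML"), log_response = TRUE,
                    group = "plot_id") {
  method <- match.arg(method)
  stopifnot(is.data.frame(data), response %in% names(data),
            group %in% names(data))
  y <- data[[response]]
  if (anyNA(y)) stop("response contains NA; subset to complete rows first")
  if (log_response && any(y <= 0)) {
    stop("response must be positive for the log transform")
  }
  if (length(unique(data[[group]])) < 2) stop("need at least 2 plots")

  lhs <- if (log_response) sprintf("log(%s)", response) else response
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  form <- stats::as.formula(
    sprintf("%s ~ %s + (1 | %s)", lhs, rhs, group))

  fit <- lme4::lmer(form, data = data, REML = (method == "REML"),
                    control = lme4::lmerControl(
                      check.conv.singular = "ignore"))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  n <- stats::nobs(fit)
  rank_x <- length(beta)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - rank_x)
  ll <- stats::logLik(fit)
  out <- list(
    model = fit,
    terms = terms,
    method = method,
    response = response,
    n = n,
    K = as.integer(attr(ll, "df")),  # fixed effects + plot var + residual var
    logLik = as.numeric(ll),
    coefficients = data.frame(term = names(beta), estimate = unname(beta),
                              se = unname(se), t = unname(tval),
                              p = unname(pval)),
    singular = lme4::isSingular(fit)
  )
  class(out) <- "lmm_fit"
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), n = %d, K = %d, logLik = %.3f%s\n",
              x$method, x$n, x$K, x$logLik,
              if (x$singular) " [singular: zero plot variance]" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2K + 2K(K + 1) / (n - K - 1)`. Converges to AIC as
#' n grows; requires `n > K + 1`.
#'
#' @param object An `lmm_fit`, or a numeric log-likelihood (then `K` and
#'   `n` must be given).
#' @param K Number of estimable parameters.
#' @param n Number of observations.
#' @return AICc value.
#' @export
aicc <- function(object, K = NULL, n = NULL) {
  if (inherits(object, "lmm_fit")) {
    ll <- object$logLik
    K <- object$K
    n <- object$n
  } else {
    ll <- as.numeric(object)
    stopifnot(!is.null(K), !is.null(n))
  }
  if (n <= K + 1) stop("AICc undefined: n <= K + 1")
  -2 * ll + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Minimum adequate model rule
#'
#' Among the models within 2 AICc units of the best one, pick the one with
#' the fewest estimable parameters; break ties by lower AICc.
#'
#' @param K Integer vector of parameter counts.
#' @param aicc_values Numeric vector of AICc values (same length).
#' @param delta_max Support window (default 2 AICc units).
#' @return Index of the minimum adequate model.
#' @export
mam_select <- function(K, aicc_values, delta_max = 2) {
  stopifnot(length(K) == length(aicc_values), length(K) >= 1)
  delta <- aicc_values - min(aicc_values)
  cand <- which(delta <= delta_max)
  cand[order(K[cand], aicc_values[cand])][1]
}

#' AICc multimodel comparison
#'
#' Fits every candidate model on the common complete-row set, computes
#' AICc (from ML likelihoods by default, since REML likelihoods are not
#' comparable across different fixed structures), AICc differences
#' `delta_i`, Akaike weights `w_i = exp(-delta_i/2) / sum(...)`, and
#' selects the minimum adequate model. Slope estimate, SE, t and p are
#' reported (from a REML refit) for univariate models; full coefficient
#' tables for every model are kept in the `fits` attribute.
#'
#' @param data data.frame with response, covariates and `plot_id`.
#' @param model_set Named list of character vectors of fixed terms;
#'   `character(0)` entries are null models. See [plot_model_set()] and
#'   [neighborhood_model_set()].
#' @param response Response column (default `"td"`).
#' @param aicc_on `"ML"` (default) or `"REML"`: which likelihood enters
#'   AICc.
#' @param ... Passed to [fit_lmm()].
#' @return data.frame of class `model_comparison`, one row per model,
#'   ordered by AICc: `model`, `K`, `AICc`, `delta`, `weight`,
#'   `estimate`, `se`, `t`, `p`, `singular`, `mam` (logical). Attributes:
#'   `fits` (REML fits, named), `n`.
#' @export
compare_models <- function(data, model_set, response = "td",
                           aicc_on = c("ML", "REML"), ...) {
  aicc_on <- match.arg(aicc_on)
  stopifnot(is.list(model_set), length(model_set) >= 2,
            !is.null(names(model_set)))
  vars <- unique(c(response, "plot_id",
                   unlist(lapply(model_set, function(tt) {
                     all.vars(stats::as.formula(
                       paste("~", paste(c("1", tt), collapse = "+"))))
                   }))))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  data <- data[keep, , drop = FALSE]

  rows <- list()
  fits <- list()
  for (nm in names(model_set)) {
    tt <- model_set[[nm]]
    ml <- tryCatch(
      fit_lmm(data, tt, response = response, method = "ML", ...),
      error = function(e) e)
    reml <- tryCatch(
      fit_lmm(data, tt, response = response, method = "REML", ...),
      error = function(e) e)
    if (inherits(ml, "error") || inherits(reml, "error")) {
      warning("model '", nm, "' failed to fit and was dropped: ",
              conditionMessage(if (inherits(ml, "error")) ml else reml))
      next
    }
    base <- if (aicc_on == "ML") ml else reml
    slope <- if (length(tt) == 1) {
      reml$coefficients[reml$coefficients$term == tt, , drop = FALSE]
    } else {
      data.frame(term = NA, estimate = NA_real_, se = NA_real_,
                 t = NA_real_, p = NA_real_)
    }
    rows[[nm]] <- data.frame(
      model = nm, K = base$K, AICc = aicc(base),
      estimate = slope$estimate[1], se = slope$se[1], t = slope$t[1],
      p = slope$p[1], singular = reml$singular)
    fits[[nm]] <- reml
  }
  if (length(rows) == 0) stop("no model could be fitted")
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- exp(-tab$delta / 2) / sum(exp(-tab$delta / 2))
  tab$mam <- seq_len(nrow(tab)) == mam_select(tab$K, tab$AICc)
  tab <- tab[order(tab$AICc),
             c("model", "K", "AICc", "delta", "weight", "estimate", "se",
               "t", "p", "singular", "mam")]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  attr(tab, "fits") <- fits
  attr(tab, "n") <- nrow(data)
  tab
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("AICc model comparison, n = %d (MAM: %s)\n", attr(x, "n"),
              x$model[x$mam]))
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Sequential variance decomposition of two correlated predictors
#'
#' Fits the nested maximum-likelihood sequence null -> +first -> +both in
#' both orders and reports the likelihood-ratio p-value of each added
#' term, separating the unique from the shared explanatory contribution
#' of two correlated predictors. Joint-model slope estimates and SEs come
#' from the REML fit of the two-predictor model.
#'
#' @param data data.frame (complete rows are taken internally).
#' @param pred1,pred2 Column names of the two predictors.
#' @param response Response column (default `"td"`).
#' @param ... Passed to [fit_lmm()].
#' @return List of class `seq_decomposition`: `orders` (data.frame: order,
#'   term, LR chi-square, df, p), `joint` (REML coefficient table of the
#'   two-predictor model), `r` (Pearson correlation of the predictors),
#'   `n`.
#' @export
sequential_decomposition <- function(data, pred1, pred2, response = "td",
                                     ...) {
  stopifnot(all(c(pred1, pred2, response, "plot_id") %in% names(data)))
  keep <- stats::complete.cases(
    data[, c(pred1, pred2, response, "plot_id")])
  data <- data[keep, , drop = FALSE]
  r <- stats::cor(data[[pred1]], data[[pred2]])
  if (!is.finite(r) || abs(r) > 0.99) {
    stop("predictors collinear (|r| > 0.99): sequential decomposition ",
         "cannot separate them")
  }
  lrt <- function(small, big) {
    stat <- 2 * (big$logLik - small$logLik)
    df <- big$K - small$K
    data.frame(chisq = stat, df = df,
               p = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  m0 <- fit_lmm(data, character(0), response = response, method = "ML", ...)
  one_order <- function(first, second) {
    m1 <- fit_lmm(data, first, response = response, method = "ML", ...)
    m2 <- fit_lmm(data, c(first, second), response = response,
                  method = "ML", ...)
    rbind(cbind(order = paste(first, "then", second), term = first,
                lrt(m0, m1)),
          cbind(order = paste(first, "then", second), term = second,
                lrt(m1, m2)))
  }
  orders <- rbind(one_order(pred1, pred2), one_order(pred2, pred1))
  rownames(orders) <- NULL
  joint <- fit_lmm(data, c(pred1, pred2), response = response,
                   method = "REML", ...)
  out <- list(orders = orders, joint = joint$coefficients, r = r,
              n = nrow(data))
  class(out) <- "seq_decomposition"
  out
}

#' @export
print.seq_decomposition <- function(x, ...) {
  cat(sprintf(
    "Sequential variance decomposition, n = %d, predictor r = %.3f\n",
    x$n, x$r))
  print(x$orders, row.names = FALSE)
  cat("Joint model (REML):\n")
  print(x$joint, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation with t-test
#'
#' Thin wrapper around [stats::cor.test()] returning the sample r, the
#' two-sided p-value and n. Zero-variance input yields NA with a warning.
#'
#' @param x,y Numeric vectors; pairs with NA are dropped.
#' @return List `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Candidate model set at the plot level
#'
#' The null model plus five univariate models, one per plot-level
#' covariate. The covariates are strongly intercorrelated along a
#' diversity gradient, so multivariate plot-level models are not
#' considered.
#'
#' @return Named list of fixed-term vectors for [compare_models()].
#' @export
plot_model_set <- function() {
  list(
    null = character(0),
    richness = "richness",
    shannon = "shannon",
    prop_castanea = "prop_castanea",
    tax_div = "tax_div",
    oak_galls = "oak_gall_pct"
  )
}

#' Candidate model set at the neighborhood level
#'
#' Fifteen models: the null model, the five plot-level univariate models,
#' five neighborhood-level univariate models (richness, Shannon, host
#' proportion, taxonomic diversity computed over the neighbor set, and
#' tree apparency), and four multivariate models combining apparency with
#' neighborhood richness or taxonomic diversity, additively and with the
#' interaction (interactions include their main effects). Apparency is
#' only weakly correlated with richness and taxonomic diversity at this
#' level, which is what makes the multivariate models admissible.
#'
#' @return Named list of fixed-term vectors for [compare_models()].
#' @export
neighborhood_model_set <- function() {
  list(
    null = character(0),
    plot_richness = "richness",
    plot_shannon = "shannon",
    plot_prop_castanea = "prop_castanea",
    plot_tax_div = "tax_div",
    plot_oak_galls = "oak_gall_pct",
    nb_richness = "nb_richness",
    nb_shannon = "nb_shannon",
    nb_prop_castanea = "nb_prop_castanea",
    nb_tax_div = "nb_tax_div",
    apparency = "delta_h",
    richness_plus_apparency = c("nb_richness", "delta_h"),
    richness_x_apparency = c("nb_richness", "delta_h",
                             "nb_richness:delta_h"),
    tax_div_plus_apparency = c("nb_tax_div", "delta_h"),
    tax_div_x_apparency = c("nb_tax_div", "delta_h", "nb_tax_div:delta_h")
  )
}
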