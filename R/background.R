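#' Term specification for the background proximity model
#'
#' Describes the structure of the expected-curve GAM: linear factor terms,
#' univariate smooths (optionally interacted with a grouping factor such as
#' LAD status, one smooth per level), and tensor-product interaction smooths
#' (optionally per TAD-segment class). Only terms whose covariate columns are
#' present in the data are kept at fit time.
#'
#' @param linear Character vector of linear (factor or numeric) term names.
#' @param smooth Character vector of covariates given thin-plate regression
#'   spline smooths.
#' @param smooth_by Optional factor column name; each smooth is duplicated
#'   per level (`s(x, by = f)`).
#' @param tensors List of character pairs given tensor-product interaction
#'   smooths (`ti`).
#' @param tensor_by Optional factor column name for the tensor interactions.
#' @param k Basis dimension of univariate smooths (default 10).
#' @param tk Marginal basis dimension of tensor smooths (default 5).
#' @return An object of class `gam_terms`.
#' @export
gam_terms <- function(linear = character(),
                      smooth = character(), smooth_by = NULL,
                      tensors = list(), tensor_by = NULL,
                      k = 10L, tk = 5L) {
  stopifnot(k >= 4L, tk >= 3L)
  structure(list(linear = linear, smooth = smooth, smooth_by = smooth_by,
                 tensors = tensors, tensor_by = tensor_by, k = k, tk = tk),
            class = "gam_terms")
}

#' Default background-model terms
#'
#' The full covariate structure of the expected proximity curve: linear
#' factors for fragile sites, LAD status, repeat class and chromatin state;
#' thin-plate smooths of replication timing, GC, TAD recurrence,
#' TAD-boundary recurrence and gene density, each interacted with LAD
#' status; and tensor-product interactions (gene density x TAD recurrence,
#' gene density x RT, RT x TAD recurrence), each per TAD-segment class.
#'
#' Default basis dimensions are 5 (univariate) and 3 (tensor marginals):
#' sized so that the model's total flexibility stays well below the number
#' of independent covariate blocks of a compact genome, which keeps the
#' background fit from absorbing localized breakpoint clusters. For
#' genome-scale data with thousands of covariate blocks the conventional
#' larger bases (k = 10, tk = 5) are appropriate.
#'
#' @inheritParams gam_terms
#' @return A `gam_terms` object.
#' @export
default_gam_terms <- function(k = 5L, tk = 3L) {
  gam_terms(
    linear = c("FS", "LAD", "repClass", "ChromMark"),
    smooth = c("RT", "GC", "TAD_recurr", "TADB_recurr", "GeneDensity"),
    smooth_by = "LAD",
    tensors = list(c("GeneDensity", "TAD_recurr"),
                   c("GeneDensity", "RT"),
                   c("RT", "TAD_recurr")),
    tensor_by = "TADsegm_class",
    k = k, tk = tk)
}

# Build the mgcv formula string from a gam_terms spec, keeping only terms
# whose columns exist in `data`; factor by-variables are coerced to factor.
.build_formula <- function(terms, data) {
  have <- function(v) all(v %in% names(data))
  parts <- character()
  dropped <- character()
  for (v in terms$linear) {
    if (have(v)) parts <- c(parts, v) else dropped <- c(dropped, v)
  }
  sby <- terms$smooth_by
  if (!is.null(sby) && !sby %in% names(data)) sby <- NULL
  for (v in terms$smooth) {
    if (!have(v)) { dropped <- c(dropped, v); next }
    parts <- c(parts,
               if (is.null(sby))
                 sprintf("s(%s, k = %d)", v, terms$k)
               else
                 sprintf("s(%s, by = %s, k = %d)", v, sby, terms$k))
  }
  tby <- terms$tensor_by
  if (!is.null(tby) && !tby %in% names(data)) tby <- NULL
  for (pr in terms$tensors) {
    if (!have(pr)) { dropped <- c(dropped, paste(pr, collapse = ":")); next }
    parts <- c(parts,
               if (is.null(tby))
                 sprintf("ti(%s, %s, k = %d)", pr[1L], pr[2L], terms$tk)
               else
                 sprintf("ti(%s, %s, by = %s, k = %d)", pr[1L], pr[2L], tby,
                         terms$tk))
  }
  if (length(dropped)) {
    warning("terms dropped (columns absent): ", paste(dropped, collapse = ", "))
  }
  if (!length(parts)) parts <- "1"
  stats::as.formula(paste(".y ~", paste(parts, collapse = " + ")),
                    env = environment())
}

#' Fit the expected background proximity curve
#'
#' Fits a Gamma-family GAM with identity link to the observed proximity
#' curve values at breakpoint resolution (one row per breakpoint). Proximity
#' values are non-positive by construction while the Gamma family needs a
#' strictly positive response, so the model is fitted to the reversed-sign
#' response `y = max(-bppc, eps)` and predictions are sign-reversed back;
#' the curve's shape is unchanged by this convention.
#'
#' Smoothing parameters are selected by REML (default) or GCV. For large
#' cohorts (`n > bam_threshold`) the fit uses `mgcv::bam` with discrete
#' covariate methods, which is the standard estimator for big additive
#' models and agrees with `mgcv::gam` to sampling accuracy.
#'
#' @param covariates Covariate data frame from [annotate_breakpoints()], one
#'   row per breakpoint.
#' @param bppc Observed smoothed proximity values aligned with `covariates`
#'   (non-positive).
#' @param terms A [gam_terms()] spec; defaults to [default_gam_terms()]
#'   restricted to available columns.
#' @param method Smoothness selection: `"REML"` (default) or `"GCV.Cp"`.
#' @param eps Positivity floor for the reversed-sign response.
#' @param bam_threshold Row count above which `mgcv::bam(discrete = TRUE)`
#'   is used.
#' @return An object of class `bppc_gam` wrapping the mgcv fit, with the
#'   fitted expected curve in `$expected` (on the original, non-positive
#'   scale).
#' @export
fit_background <- function(covariates, bppc, terms = default_gam_terms(),
                           method = c("REML", "GCV.Cp"), eps = 1e-6,
                           bam_threshold = 4000L) {
  method <- match.arg(method)
  if (nrow(covariates) != length(bppc)) {
    stop("covariates and bppc must be aligned")
  }
  data <- covariates
  data$.y <- pmax(-bppc, eps)
  # drop empty factor levels so by-smooths are not built for absent levels
  for (nm in names(data)) if (is.factor(data[[nm]])) {
    data[[nm]] <- droplevels(data[[nm]])
  }
  fml <- .build_formula(terms, covariates)
  has_smooth <- any(grepl("(^|[+ ])(s|ti)\\(",
                          attr(stats::terms(fml), "term.labels")))
  n <- nrow(data)
  fit <- if (n > bam_threshold && has_smooth) {
    mgcv::bam(fml, data = data, family = stats::Gamma(link = "identity"),
              method = if (method == "REML") "fREML" else "GCV.Cp",
              discrete = TRUE)
  } else {
    mgcv::gam(fml, data = data, family = stats::Gamma(link = "identity"),
              method = method)
  }
  if (!fit$converged) {
    stop("background GAM did not converge; deviance = ", fit$deviance)
  }
  nd <- fit$null.deviance
  if (!is.finite(nd)) {
    # some fast-fitting paths skip it; the intercept-only Gamma/identity
    # MLE of the mean is the sample mean, so the null deviance is direct
    nd <- sum(fit$family$dev.resids(data$.y, rep(mean(data$.y), n),
                                    rep(1, n)))
  }
  structure(list(fit = fit, terms = terms, n = n, eps = eps,
                 data = data,
                 expected = -as.numeric(stats::fitted(fit)),
                 null_deviance = nd,
                 residual_deviance = fit$deviance),
            class = "bppc_gam")
}

#' Explained deviance of a background fit
#'
#' `(null deviance - residual deviance) / null deviance`, the GAM analogue
#' of R-squared.
#'
#' @param object A `bppc_gam` fit.
#' @return Fraction in `[0, 1]`.
#' @export
explained_deviance <- function(object) {
  stopifnot(inherits(object, "bppc_gam"))
  if (object$null_deviance == 0) stop("null deviance is zero; undefined")
  (object$null_deviance - object$residual_deviance) / object$null_deviance
}

#' Per-term significance of the background fit
#'
#' Wald-type tests per model term using the Bayesian (penalized) covariance
#' matrix of the coefficient estimates: smooth and tensor terms from the
#' smooth-term table, parametric factor terms from the joint parametric
#' term table.
#'
#' @param object A `bppc_gam` fit.
#' @return Data frame with columns `term`, `type` (`parametric`/`smooth`),
#'   `statistic`, `p_value` (`NA` where a term's covariance block is
#'   singular or the term was dropped).
#' @export
term_significance <- function(object) {
  stopifnot(inherits(object, "bppc_gam"))
  sm <- summary(object$fit)
  out <- list()
  stat_col <- function(tab) {  # "F" or "Chi.sq" depending on scale handling
    nm <- intersect(c("F", "Chi.sq"), colnames(tab))[1L]
    tab[, nm]
  }
  if (!is.null(sm$pTerms.table) && nrow(sm$pTerms.table)) {
    out[[1L]] <- data.frame(term = rownames(sm$pTerms.table),
                            type = "parametric",
                            statistic = stat_col(sm$pTerms.table),
                            p_value = sm$pTerms.table[, "p-value"],
                            stringsAsFactors = FALSE)
  }
  if (!is.null(sm$s.table) && nrow(sm$s.table)) {
    out[[2L]] <- data.frame(term = rownames(sm$s.table),
                            type = "smooth",
                            statistic = stat_col(sm$s.table),
                            p_value = sm$s.table[, "p-value"],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Partial effect of one model term
#'
#' Evaluates the contribution of a single smooth or tensor term over a grid,
#' with the Bayesian standard-error band (two standard errors above and
#' below). Remaining covariates are held at their median (numeric) or
#' reference level (factor). Grid points outside the observed data range are
#' flagged as extrapolation.
#'
#' @param object A `bppc_gam` fit.
#' @param term Covariate name (for a 1-D smooth) or character pair (tensor).
#' @param by_level Level of the `by` factor to evaluate (default: first).
#' @param n Grid size per dimension (default 100; 40 for surfaces).
#' @return Data frame with grid coordinates, `effect`, `se`, `lower`,
#'   `upper` and `extrapolated`. Effects are on the reversed-sign working
#'   scale of the fit.
#' @export
partial_effects <- function(object, term, by_level = NULL, n = NULL) {
  stopifnot(inherits(object, "bppc_gam"))
  fit <- object$fit
  data <- object$data
  vars <- term
  is2d <- length(vars) == 2L
  if (is.null(n)) n <- if (is2d) 40L else 100L
  for (v in vars) if (!v %in% names(data)) stop("unknown term variable: ", v)
  grid_of <- function(v) seq(min(data[[v]]), max(data[[v]]), length.out = n)
  newd <- if (is2d) {
    expand.grid(grid_of(vars[1L]), grid_of(vars[2L]))
  } else {
    data.frame(grid_of(vars[1L]))
  }
  names(newd) <- vars
  for (nm in setdiff(names(data), c(vars, ".y"))) {
    col <- data[[nm]]
    newd[[nm]] <- if (is.factor(col)) factor(levels(col)[1L],
                                             levels = levels(col))
    else stats::median(col)
  }
  by_var <- if (is2d) object$terms$tensor_by else object$terms$smooth_by
  if (!is.null(by_var) && by_var %in% names(data)) {
    lv <- levels(data[[by_var]])
    newd[[by_var]] <- factor(if (is.null(by_level)) lv[1L] else by_level,
                             levels = lv)
  }
  pr <- mgcv::predict.gam(fit, newdata = newd, type = "terms",
                          se.fit = TRUE)
  # pick the term column matching the requested variables (and by level)
  cols <- colnames(pr$fit)
  pat <- if (is2d) paste0("ti\\(", vars[1L], ",", vars[2L], "\\)")
  else paste0("s\\(", vars[1L], "\\)")
  hit <- grep(pat, cols)
  if (!is.null(by_var) && length(hit) > 1L) {
    lvl <- as.character(newd[[by_var]][1L])
    hit <- hit[grepl(lvl, cols[hit], fixed = TRUE)]
  }
  if (!length(hit)) stop("no fitted term matches ", paste(vars, collapse = ","))
  eff <- rowSums(pr$fit[, hit, drop = FALSE])
  se <- sqrt(rowSums(pr$se.fit[, hit, drop = FALSE]^2))
  out <- newd[vars]
  out$effect <- eff
  out$se <- se
  out$lower <- eff - 2 * se
  out$upper <- eff + 2 * se
  out$extrapolated <- FALSE
  for (v in vars) {
    out$extrapolated <- out$extrapolated |
      out[[v]] < min(data[[v]]) | out[[v]] > max(data[[v]])
  }
  out
}

#' Predict expected proximity values
#'
#' @param object A `bppc_gam` fit.
#' @param newdata Optional covariate data frame; defaults to training data.
#' @param ... Unused.
#' @return Expected proximity values on the original (non-positive) scale.
#' @export
predict.bppc_gam <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$expected)
  -as.numeric(mgcv::predict.gam(object$fit, newdata = newdata,
                                type = "response"))
}

#' @export
coef.bppc_gam <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.bppc_gam <- function(object, type = "deviance", ...) {
  stats::residuals(object$fit, type = type)
}

#' @export
print.bppc_gam <- function(x, ...) {
  cat("Background proximity GAM (Gamma family, identity link)\n")
  cat("  n =", x$n, "breakpoints;",
      length(stats::coef(x$fit)), "coefficients\n")
  cat("  explained deviance:",
      sprintf("%.1f%%", 100 * explained_deviance(x)), "\n")
  invisible(x)
}

#' @export
summary.bppc_gam <- function(object, ...) {
  structure(list(expl_dev = explained_deviance(object),
                 terms = term_significance(object),
                 n = object$n),
            class = "summary.bppc_gam")
}

#' @export
print.summary.bppc_gam <- function(x, ...) {
  cat("Background proximity GAM: n =", x$n, "breakpoints\n")
  cat("Explained deviance:", sprintf("%.1f%%", 100 * x$expl_dev), "\n\n")
  cat("Term significance (Bayesian-covariance Wald tests):\n")
  print(x$terms, digits = 3)
  invisible(x)
}

#' @export
plot.bppc_gam <- function(x, ...) {
  mgcv::plot.gam(x$fit, ...)
  invisible(x)
}
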