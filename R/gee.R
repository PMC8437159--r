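#' Fit a linear GEE with exchangeable working correlation
#'
#' Marginal linear model estimated by generalized estimating equations with
#' an exchangeable (compound-symmetry) working correlation across
#' observations sharing a cluster, and cluster-robust (sandwich) standard
#' errors. The common correlation is re-estimated at each iteration by the
#' moment estimator from standardized residual cross-products; the
#' exchangeable inverse is applied in closed form, so clusters of several
#' hundred households cost no matrix inversion.
#'
#' With one observation per cluster the working correlation is
#' unidentifiable and the point estimates reduce to ordinary least squares.
#' Confidence intervals are Wald with the normal 1.96 quantile and no
#' small-sample cluster correction by default (the optional correction
#' multiplies the sandwich by m/(m-1)).
#'
#' @param design a `dietshock_design` from [encode_with_missing_indicators()],
#'   or any list with `y`, `X` (including intercept), `cluster`.
#' @param correlation `"exchangeable"` (default) or `"independence"`.
#' @param small_sample_correction logical; apply the m/(m-1) sandwich
#'   inflation (off by default, matching the published analysis).
#' @param fixed_alpha optional fixed working correlation; when given, the
#'   moment estimation step is skipped (a `fixed_alpha` of 0 reproduces the
#'   independence fit exactly).
#' @param max_iter,tol iteration control.
#' @return object of class `dietshock_gee`: a list with `coefficients`
#'   (data.frame: `term`, `estimate`, `se`, `ci_low`, `ci_high`, `p`),
#'   `alpha` (estimated common correlation), `n`, `n_clusters`, `converged`,
#'   `vcov`, `correlation`, and the design's `term_map` when present.
#' @export
fit_gee_linear <- function(design, correlation = c("exchangeable",
                                                   "independence"),
                           small_sample_correction = FALSE,
                           fixed_alpha = NULL, max_iter = 100L, tol = 1e-8) {
  correlation <- match.arg(correlation)
  y <- as.numeric(design$y)
  X <- as.matrix(design$X)
  cl <- as.character(design$cluster)
  N <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == N, length(cl) == N)

  clusters <- unique(cl)
  m <- length(clusters)
  if (m < 2L)
    abort(paste0("only ", m, " cluster present; GEE clustering is ",
                 "unidentifiable - refit with correlation = \"independence\" ",
                 "and household-level clusters"), "dietshock_model_error")
  sds <- apply(X, 2L, stats::sd)
  zv <- names(which(sds == 0 & colnames(X) != "(intercept)"))
  if (length(zv))
    abort(paste0("zero-variance design column(s): ",
                 paste(zv, collapse = ", ")), "dietshock_model_error")
  if (qr(X)$rank < p)
    abort("design matrix is rank deficient (collinear columns)",
          "dietshock_model_error")

  idx <- split(seq_len(N), cl)
  ns <- lengths(idx)

  beta <- qr.solve(X, y)  # OLS start (also the independence solution)
  alpha <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    e <- y - drop(X %*% beta)
    phi <- sum(e^2) / (N - p)
    if (!is.null(fixed_alpha)) {
      alpha_new <- fixed_alpha
    } else if (correlation == "exchangeable" && any(ns > 1L)) {
      cross <- 0
      for (ii in idx) {
        ei <- e[ii]
        cross <- cross + (sum(ei)^2 - sum(ei^2)) / 2
      }
      npairs <- sum(ns * (ns - 1) / 2)
      alpha_new <- (cross / max(npairs - p, 1)) / phi
      lower <- -1 / (max(ns) - 1) + 1e-6
      alpha_new <- min(max(alpha_new, lower), 0.999)
    } else alpha_new <- 0

    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      yi <- y[ii]
      ni <- length(ii)
      ci <- alpha_new / (1 + (ni - 1) * alpha_new)
      sX <- colSums(Xi)
      A <- A + (crossprod(Xi) - ci * tcrossprod(sX)) / (1 - alpha_new)
      b <- b + (crossprod(Xi, yi) - ci * sX * sum(yi)) / (1 - alpha_new)
    }
    beta_new <- drop(solve(A, b))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    alpha <- alpha_new
    if (delta < tol) { converged <- TRUE; break }
  }

  # sandwich: A^-1 (sum_i g_i g_i') A^-1 with g_i = X_i' R_i^-1 e_i
  e <- y - drop(X %*% beta)
  A <- matrix(0, p, p)
  M <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    ei <- e[ii]
    ni <- length(ii)
    ci <- alpha / (1 + (ni - 1) * alpha)
    sX <- colSums(Xi)
    A <- A + (crossprod(Xi) - ci * tcrossprod(sX)) / (1 - alpha)
    gi <- (crossprod(Xi, ei) - ci * sX * sum(ei)) / (1 - alpha)
    M <- M + tcrossprod(gi)
  }
  Ainv <- solve(A)
  V <- Ainv %*% M %*% Ainv
  if (small_sample_correction) V <- V * m / (m - 1)

  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(
    term = colnames(X),
    estimate = unname(beta),
    se = unname(se),
    ci_low = unname(beta - 1.96 * se),
    ci_high = unname(beta + 1.96 * se),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE)

  if (!converged)
    warning("GEE did not converge in ", max_iter, " iterations")
  structure(list(coefficients = coefs, vcov = V, alpha = alpha,
                 n = N, n_clusters = m, converged = converged,
                 correlation = correlation,
                 term_map = design$term_map %||% NULL,
                 n_dropped_outcome = design$n_dropped_outcome %||% 0L,
                 outcome = design$outcome %||% NA_character_),
            class = "dietshock_gee")
}

#' @export
print.dietshock_gee <- function(x, ...) {
  cat("Linear GEE (", x$correlation, " working correlation)\n", sep = "")
  cat("n =", x$n, " clusters =", x$n_clusters,
      " alpha =", signif(x$alpha, 3),
      " converged =", x$converged, "\n\n")
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), se = signif(se, 4),
                  ci_low = signif(ci_low, 4), ci_high = signif(ci_high, 4),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Joint Wald test for a set of coefficients
#'
#' The covariance submatrix is inverted by a Moore-Penrose pseudoinverse and
#' the test's degrees of freedom are its numerical rank: with m clusters the
#' sandwich has rank at most m, so country-specific fits (2 clusters) would
#' otherwise make multi-level joint tests singular.
#'
#' @param fit a `dietshock_gee`.
#' @param columns design-column names tested jointly against zero.
#' @return list with `statistic`, `df`, `p`.
#' @export
wald_joint <- function(fit, columns) {
  i <- match(columns, fit$coefficients$term)
  if (anyNA(i))
    abort(paste0("unknown coefficient(s): ",
                 paste(columns[is.na(i)], collapse = ", ")),
          "dietshock_model_error")
  b <- fit$coefficients$estimate[i]
  Vi <- fit$vcov[i, i, drop = FALSE]
  sv <- svd(Vi)
  pos <- sv$d > max(sv$d) * 1e-9
  pinv <- sv$v[, pos, drop = FALSE] %*%
    (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  stat <- drop(t(b) %*% pinv %*% b)
  df <- sum(pos)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df,
                                                    lower.tail = FALSE))
}

# internal: encode + fit, silently pruning design columns for levels absent
# in this (sub)sample so country-specific fits do not trip the zero-variance
# check; pruned columns are recorded on the fit.
fit_terms <- function(records, terms, outcome, cluster = "site", ...) {
  design <- encode_with_missing_indicators(records, terms, outcome, cluster)
  sds <- apply(design$X, 2L, stats::sd)
  drop <- colnames(design$X)[sds == 0 & colnames(design$X) != "(intercept)"]
  if (length(drop)) {
    design$X <- design$X[, setdiff(colnames(design$X), drop), drop = FALSE]
    design$term_map <- design$term_map[!design$term_map$column %in% drop, ,
                                       drop = FALSE]
  }
  fit <- fit_gee_linear(design, ...)
  fit$pruned_columns <- drop
  fit
}

#' Univariate covariate screen at a liberal p threshold
#'
#' Fits each candidate confounder alone (same outcome, same GEE clustering)
#' and keeps it when the joint Wald p across its non-missing levels is below
#' `alpha` (default 0.20). Exposures and forced terms are retained
#' regardless. Candidates that are entirely missing are excluded with a
#' warning.
#'
#' @param records scored survey data.frame.
#' @param outcome `"dds"` or `"pdqs"`.
#' @param terms named list of [term_spec()]s.
#' @param alpha screening threshold.
#' @param cluster cluster column.
#' @param ... passed to [fit_gee_linear()].
#' @return list with `selected` (term names for the multivariate model),
#'   `screen` (data.frame: `term`, `role`, `p`, `df`, `kept`) and
#'   `univariate_fits` (named list of `dietshock_gee`).
#' @export
univariate_screen <- function(records, outcome = c("dds", "pdqs"),
                              terms = default_model_terms(), alpha = 0.20,
                              cluster = "site", ...) {
  outcome <- match.arg(outcome)
  roles <- vapply(terms, `[[`, "", "role")
  fits <- list()
  rows <- list()
  for (tn in names(terms)) {
    all_missing <- all(is.na(records[[terms[[tn]]$field]]))
    if (all_missing) {
      warning("candidate '", tn, "' has no observed values; excluded")
      rows[[tn]] <- data.frame(term = tn, role = roles[[tn]], p = NA_real_,
                               df = 0L, kept = FALSE, stringsAsFactors = FALSE)
      next
    }
    fit <- fit_terms(records, terms[tn], outcome, cluster, ...)
    fits[[tn]] <- fit
    tmap <- fit$term_map
    cols <- tmap$column[tmap$term == tn & !tmap$is_missing_col]
    if (!length(cols)) {  # every level pruned or missing-only
      rows[[tn]] <- data.frame(term = tn, role = roles[[tn]], p = NA_real_,
                               df = 0L, kept = FALSE, stringsAsFactors = FALSE)
      next
    }
    w <- wald_joint(fit, cols)
    kept <- roles[[tn]] != "candidate" || w$p < alpha
    rows[[tn]] <- data.frame(term = tn, role = roles[[tn]], p = w$p,
                             df = w$df, kept = kept, stringsAsFactors = FALSE)
  }
  screen <- do.call(rbind, rows)
  rownames(screen) <- NULL
  list(selected = screen$term[screen$kept], screen = screen,
       univariate_fits = fits)
}

#' Specify an association model
#'
#' @param outcome `"dds"` or `"pdqs"`.
#' @param scope `"combined"` (all six sites, cluster = site) or
#'   `"per_country"` (one model per country over its two sites).
#' @param terms named list of [term_spec()]s.
#' @param alpha univariate screening threshold.
#' @param cluster cluster column (`"site"` is the published choice;
#'   `"household_id"` gives the household-level sensitivity mode).
#' @param small_sample_correction see [fit_gee_linear()].
#' @return list of class `dietshock_model_spec`.
#' @export
model_spec <- function(outcome = c("dds", "pdqs"),
                       scope = c("combined", "per_country"),
                       terms = default_model_terms(), alpha = 0.20,
                       cluster = "site", small_sample_correction = FALSE) {
  structure(list(outcome = match.arg(outcome), scope = match.arg(scope),
                 terms = terms, alpha = alpha, cluster = cluster,
                 small_sample_correction = small_sample_correction),
            class = "dietshock_model_spec")
}

# internal: tidy one fit into rows of the results table
tidy_fit <- function(fit, model, scope_label, outcome) {
  tmap <- fit$term_map
  co <- fit$coefficients
  keep <- co$term != "(intercept)"
  co <- co[keep, , drop = FALSE]
  i <- match(co$term, tmap$column)
  data.frame(scope = scope_label, outcome = outcome, model = model,
             term = tmap$term[i], level = tmap$level[i],
             estimate = co$estimate, se = co$se, ci_low = co$ci_low,
             ci_high = co$ci_high, p = co$p,
             n = fit$n, n_clusters = fit$n_clusters,
             stringsAsFactors = FALSE)
}

#' Run the full model-building pipeline (screen, assemble, fit)
#'
#' Reproduces the published model-building rules: every candidate is fit
#' univariately; the multivariate model contains the five price exposures,
#' the candidates passing the P < 0.20 screen, and the forced terms (crop
#' production, household size), all missing-indicator encoded; estimation is
#' exchangeable-correlation linear GEE clustered by site. With
#' `scope = "per_country"` the screen and fit are repeated within each
#' country (both of its sites required).
#'
#' @param records scored survey data.frame.
#' @param spec a [model_spec()].
#' @return list of class `dietshock_model_results`: `results` (tidy
#'   data.frame over univariate and multivariate rows), `screens` (per scope),
#'   `fits` (multivariate `dietshock_gee` per scope).
#' @export
build_and_fit <- function(records, spec = model_spec()) {
  cb <- default_codebook()
  scopes <- if (spec$scope == "combined") list(combined = records)
  else {
    countries <- sort(unique(records$country[!is.na(records$country)]))
    stats::setNames(lapply(countries, function(cc)
      records[!is.na(records$country) & records$country == cc, ,
              drop = FALSE]), countries)
  }
  all_rows <- list()
  screens <- list()
  fits <- list()
  for (lab in names(scopes)) {
    rec <- scopes[[lab]]
    if (spec$scope == "per_country") {
      n_sites <- length(unique(rec$site[!is.na(rec$site)]))
      if (n_sites < 2L)
        abort(paste0("country ", lab, " has ", n_sites,
                     " site(s); country models require both sites"),
              "dietshock_model_error")
    }
    scr <- univariate_screen(rec, spec$outcome, spec$terms, spec$alpha,
                             spec$cluster,
                             small_sample_correction = spec$small_sample_correction)
    screens[[lab]] <- scr$screen
    mv_terms <- spec$terms[scr$selected]
    fit <- fit_terms(rec, mv_terms, spec$outcome, spec$cluster,
                     small_sample_correction = spec$small_sample_correction)
    fits[[lab]] <- fit
    uni_rows <- lapply(names(scr$univariate_fits), function(tn)
      tidy_fit(scr$univariate_fits[[tn]], "univariate", lab, spec$outcome))
    all_rows[[lab]] <- rbind(do.call(rbind, uni_rows),
                             tidy_fit(fit, "multivariate", lab, spec$outcome))
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  structure(list(results = results, screens = screens, fits = fits,
                 spec = spec),
            class = "dietshock_model_results")
}

#' Format model results in the published table style
#'
#' Renders `estimate (ci_low to ci_high)` strings with significance stars
#' (* P < 0.05, ** P < 0.01, *** P < 0.001) and `"ref"` rows for reference
#' levels of categorical terms.
#'
#' @param results a `dietshock_model_results` or its tidy `results`
#'   data.frame.
#' @param terms the term list used (for reference levels).
#' @return data.frame with columns `scope`, `outcome`, `term`, `level` and one
#'   formatted column per model (`univariate`, `multivariate`).
#' @export
results_report <- function(results, terms = default_model_terms()) {
  df <- if (inherits(results, "dietshock_model_results")) results$results
        else results
  if (!nrow(df)) abort("no results to report", "dietshock_model_error")
  fmt <- function(est, lo, hi, p) {
    stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                    ifelse(p < 0.05, "*", "")))
    sprintf("%.2f (%.2f to %.2f)%s", round_half_up(est, 2),
            round_half_up(lo, 2), round_half_up(hi, 2), stars)
  }
  df$cell <- fmt(df$estimate, df$ci_low, df$ci_high, df$p)
  ref_level <- function(tn) {
    tm <- terms[[tn]]
    if (is.null(tm)) return(NA_character_)
    switch(tm$type, price = "no_change_or_decreased", yesno = "no",
           categorical = tm$ref %||% "", continuous = NA_character_)
  }
  out <- list()
  for (sc in unique(df$scope)) for (oc in unique(df$outcome)) {
    sub <- df[df$scope == sc & df$outcome == oc, , drop = FALSE]
    if (!nrow(sub)) next
    for (tn in unique(sub$term)) {
      tsub <- sub[sub$term == tn, , drop = FALSE]
      rl <- ref_level(tn)
      rows <- if (!is.na(rl) && rl != "") {
        data.frame(scope = sc, outcome = oc, term = tn, level = rl,
                   univariate = "ref", multivariate = "ref",
                   stringsAsFactors = FALSE)
      } else NULL
      for (lv in unique(tsub$level)) {
        lsub <- tsub[tsub$level == lv, , drop = FALSE]
        pick <- function(mod) {
          v <- lsub$cell[lsub$model == mod]
          if (length(v)) v[1] else ""
        }
        rows <- rbind(rows, data.frame(
          scope = sc, outcome = oc, term = tn, level = lv,
          univariate = pick("univariate"), multivariate = pick("multivariate"),
          stringsAsFactors = FALSE))
      }
      out[[paste(sc, oc, tn)]] <- rows
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
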