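#' Assemble a used/available design table
#'
#' Stacks used rows (case = 1) over available rows (case = 0), coerces
#' categorical covariates to factors with the stated reference levels first
#' (soil reference blocky loam; vegetation reference barren), and drops —
#' with a count — rows flagged NA by extraction.
#'
#' @param used,available covariate data.frames with identical covariate
#'   schemas (as from [extract_covariates()]; an `.any_na` column, if
#'   present, marks rows to drop). Extra bookkeeping columns `animal_id` and
#'   `season_year` are carried through if present.
#' @param categorical_refs named map covariate -> reference level.
#' @return an `rsf_design`: list with `data` (data.frame: `case` +
#'   covariates), `refs`, `n_used`, `n_available`, `n_dropped`.
#' @export
build_design <- function(used, available,
                         categorical_refs = c(soil = "blocky_loam",
                                              vegetation = "barren")) {
  if (nrow(available) == 0) stop("zero available rows")
  meta <- c(".any_na", "animal_id", "season_year")
  cov_u <- setdiff(names(used), meta)
  cov_a <- setdiff(names(available), meta)
  if (!identical(sort(cov_u), sort(cov_a))) {
    stop("schema mismatch between used and available covariates")
  }
  used <- used[, union(cov_u, intersect(meta, names(used))), drop = FALSE]
  available <- available[, union(cov_u, intersect(meta, names(available))),
                         drop = FALSE]
  df <- rbind(cbind(case = 1, used[, names(used) != ".any_na", drop = FALSE]),
              cbind(case = 0, available[, names(available) != ".any_na",
                                        drop = FALSE]))
  flag <- c(if (".any_na" %in% names(used)) used$.any_na else
              rep(FALSE, nrow(used)),
            if (".any_na" %in% names(available)) available$.any_na else
              rep(FALSE, nrow(available)))
  flag <- flag | Reduce(`|`, lapply(df[cov_u], is.na), rep(FALSE, nrow(df)))
  n_dropped <- sum(flag)
  df <- df[!flag, , drop = FALSE]
  for (nm in intersect(cov_u, names(df))) {
    if (is.character(df[[nm]]) || is.factor(df[[nm]])) {
      lev <- sort(unique(as.character(df[[nm]])))
      ref <- categorical_refs[[nm]]
      if (!is.null(ref) && ref %in% lev) lev <- c(ref, setdiff(lev, ref))
      only_used <- setdiff(unique(as.character(df[[nm]][df$case == 1])),
                           unique(as.character(df[[nm]][df$case == 0])))
      if (length(only_used)) {
        stop("inestimable contrast: level(s) of ", nm,
             " present only in used rows: ",
             paste(only_used, collapse = ", "))
      }
      df[[nm]] <- factor(df[[nm]], levels = lev)
    }
  }
  rownames(df) <- NULL
  structure(list(data = df, refs = categorical_refs,
                 covariates = cov_u,
                 n_used = sum(df$case == 1),
                 n_available = sum(df$case == 0),
                 n_dropped = n_dropped),
            class = "rsf_design")
}

#' @export
print.rsf_design <- function(x, ...) {
  cat(sprintf("rsf_design: %d used + %d available rows (%d dropped), covariates: %s\n",
              x$n_used, x$n_available, x$n_dropped,
              paste(setdiff(x$covariates, c("animal_id", "season_year")),
                    collapse = ", ")))
  invisible(x)
}

design_formula <- function(design) {
  covs <- setdiff(design$covariates, c("animal_id", "season_year"))
  stats::reformulate(sprintf("`%s`", covs), response = "case")
}

#' Fit an exponential RSF by used-available logistic regression
#'
#' Maximizes the binomial log-likelihood of case (used = 1, available = 0)
#' against the covariates with a logit link via iteratively reweighted least
#' squares (`stats::glm`). The fitted slopes are the log selection strengths
#' of the exponential RSF w(x) = exp(beta'x); the intercept absorbs the
#' used:available sampling ratio and is not part of the relative-use
#' surface.
#'
#' @param design an `rsf_design`.
#' @param transforms optional named list recording covariate transforms
#'   (e.g. the (center, scale) of elevation, or "log1p" for distances) to be
#'   replayed at prediction time; stored verbatim in the fit.
#' @return an `rsf_fit`: `beta` (named), `vcov`, `log_likelihood`, `aic`,
#'   `n_used`, `n_available`, `k`, `converged`, `xlevels`, `transforms`.
#' @export
fit_rsf <- function(design, transforms = NULL) {
  df <- design$data
  covs <- setdiff(design$covariates, c("animal_id", "season_year"))
  for (nm in covs) {
    v <- df[[nm]]
    if (is.numeric(v) && length(unique(v)) < 2L) {
      stop("constant column: ", nm)
    }
  }
  fml <- design_formula(design)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  beta <- stats::coef(fit)
  if (any(is.na(beta))) {
    stop("rank-deficient design; aliased term(s): ",
         paste(names(beta)[is.na(beta)], collapse = ", "))
  }
  if (warned_sep && any(abs(beta[-1]) > 15)) {
    big <- names(beta)[-1][abs(beta[-1]) > 15]
    stop("perfect separation on covariate(s): ", paste(big, collapse = ", "))
  }
  # IRLS stops on relative deviance change; polish with full Newton steps so
  # the score X'(y - p) is driven to the stated optimum tolerance
  X <- stats::model.matrix(fit)
  y <- df$case
  vc <- stats::vcov(fit)
  p <- stats::fitted(fit)
  g <- drop(crossprod(X, y - p))
  for (it in seq_len(25L)) {
    if (sqrt(sum(g^2)) < 1e-8) break
    w <- p * (1 - p)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - p))
    vc <- tryCatch(solve(crossprod(X * (p * (1 - p)), X)),
                   error = function(e) vc)
  }
  dimnames(vc) <- list(names(beta), names(beta))
  eta <- drop(X %*% beta)
  loglik <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
  structure(list(
    beta = beta,
    vcov = vc,
    log_likelihood = loglik,
    n_used = design$n_used,
    n_available = design$n_available,
    k = length(beta),
    converged = fit$converged && sqrt(sum(g^2)) < 1e-6,
    gradient_norm = sqrt(sum(g^2)),
    fitted = unname(p),
    xlevels = fit$xlevels,
    refs = design$refs,
    transforms = transforms,
    formula = fml
  ), class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("rsf_fit: %d used / %d available, logL = %.2f, k = %d%s\n",
              x$n_used, x$n_available, x$log_likelihood, x$k,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$beta, 4))
  invisible(x)
}

#' Wald confidence intervals for RSF coefficients
#'
#' @param fit an `rsf_fit`.
#' @param level confidence level (default 0.95).
#' @return data.frame with `term`, `estimate`, `se`, `lower`, `upper`,
#'   `p_value` (Wald) and `significant` (interval excludes 0).
#' @export
wald_ci <- function(fit, level = 0.95) {
  if (!fit$converged) stop("fit did not converge; intervals are unreliable")
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$beta
  data.frame(term = names(est),
             estimate = unname(est),
             se = unname(se),
             lower = unname(est - z * se),
             upper = unname(est + z * se),
             p_value = unname(2 * stats::pnorm(-abs(est / se))),
             significant = unname(abs(est) - z * se > 0),
             row.names = NULL)
}

#' Predict relative probability of use across the landscape
#'
#' Evaluates w(x) = exp(sum_j beta_j x_j) over the non-intercept terms of a
#' fitted RSF on raster covariate layers. The intercept is excluded: an RSF
#' is meaningful only up to a multiplicative constant. Continuous layers
#' must already be on the model scale unless a stored transform is replayed;
#' categorical layers are expanded with the fit's own level coding. NA in
#' any required layer propagates.
#'
#' @param fit an `rsf_fit`.
#' @param layers named list of `grid_raster`s, one per model covariate
#'   (categorical covariates as their categorical raster).
#' @param apply_transforms replay the transforms stored in the fit (a named
#'   list; each element either "log1p" or a list(center=, scale=)). Default
#'   TRUE.
#' @param rescale "none" returns raw exp(beta'x); "max" divides by the
#'   largest cell value so the surface lies in (0, 1]. Because an RSF is
#'   meaningful only up to a multiplicative constant this changes nothing
#'   inferentially, and it keeps the surface well conditioned when it is fed
#'   back in as a covariate of a second-stage model.
#' @return an `rpu_raster` (`grid_raster` with attribute `model`).
#' @export
predict_rpu <- function(fit, layers, apply_transforms = TRUE,
                        rescale = c("none", "max")) {
  rescale <- match.arg(rescale)
  covs <- all.vars(fit$formula)[-1]
  missing_layer <- setdiff(covs, names(layers))
  if (length(missing_layer)) {
    stop("missing layer(s): ", paste(missing_layer, collapse = ", "))
  }
  template <- layers[[covs[1]]]
  eta <- matrix(0, nrow(template$values), ncol(template$values))
  na_mask <- matrix(FALSE, nrow(eta), ncol(eta))
  for (nm in covs) {
    r <- layers[[nm]]
    if (!rasters_aligned(r, template)) {
      stop("layer ", nm, " is not aligned with the others")
    }
    if (!is.null(fit$xlevels[[nm]])) {
      lev <- fit$xlevels[[nm]]
      if (is.null(r$levels)) stop("layer ", nm, " must be categorical")
      na_mask <- na_mask | is.na(r$values)
      for (l in lev[-1]) {           # reference level contributes 0
        coef_name <- paste0(nm, l)
        b <- fit$beta[[coef_name]]
        if (is.null(b)) next
        code <- match(l, r$levels)
        ind <- (r$values == code) + 0
        ind[is.na(ind)] <- 0
        eta <- eta + b * ind
      }
    } else {
      v <- r$values
      if (apply_transforms && !is.null(fit$transforms[[nm]])) {
        tr <- fit$transforms[[nm]]
        if (identical(tr, "log1p")) {
          v <- log1p(v)
        } else if (is.list(tr) && !is.null(tr$center)) {
          v <- (v - tr$center) / tr$scale
        }
      }
      na_mask <- na_mask | is.na(v)
      v[is.na(v)] <- 0
      eta <- eta + fit$beta[[nm]] * v
    }
  }
  out <- exp(eta)
  out[na_mask] <- NA
  if (rescale == "max") out <- out / max(out, na.rm = TRUE)
  r <- grid_raster(out, template$cell_size, template$origin)
  attr(r, "model") <- fit$formula
  r
}
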