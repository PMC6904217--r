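#' Phylogenetic generalized least squares
#'
#' Fits a linear model by maximum likelihood whose error covariance follows
#' trait evolution on a phylogeny, under either a Brownian-motion (BM) or a
#' stationary Ornstein-Uhlenbeck (OU) structure. With `structure = "auto"`
#' both are fitted and the one with the larger small-sample Akaike weight is
#' reported (ties broken toward BM, the simpler model); both candidate fits
#' are kept in the returned object.
#'
#' The scale parameter is profiled analytically; for OU the pull strength
#' alpha is profiled by bounded one-dimensional ML search on log(alpha) in
#' [-10, 10] (alpha in 1/Myr) with a three-point multistart.
#'
#' @param formula Model formula, e.g. `log10(eye_mass) ~ log10(body_mass)`.
#' @param data Data frame with species as `rownames` or in a `species`
#'   column; rows with missing values in the model variables are dropped
#'   (complete cases per analysis) and the tree pruned accordingly.
#' @param tree A `"phylo"` tree containing all analysed species.
#' @param structure `"BM"`, `"OU"`, or `"auto"`.
#' @param criterion Information criterion for `"auto"`: `"AICc"` (default)
#'   or `"AIC"`.
#' @return Object of class `"pgls"` with coefficients, standard errors,
#'   t-statistics, p-values, residuals, fitted values, `loglik`, `sigma2`
#'   (and `alpha` for OU), the selected `structure`, criterion values and
#'   weights across the compared structures, and `n`.
#' @examples
#' tr <- ape::rcoal(20)
#' d <- data.frame(x = rnorm(20), row.names = tr$tip.label)
#' d$y <- 2 * d$x + 1
#' pgls_fit(y ~ x, d, tr, structure = "BM")
#' @export
pgls_fit <- function(formula, data, tree, structure = c("auto", "BM", "OU"),
                     criterion = c("AICc", "AIC")) {
  structure <- match.arg(structure)
  criterion <- match.arg(criterion)
  data <- as.data.frame(data)
  if ("species" %in% names(data)) {
    rownames(data) <- data$species
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  species <- rownames(mf)
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown)) {
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  }
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  n <- length(y); p <- ncol(X)
  if (n < p + 2L) stop("need at least p + 2 complete cases")
  tr <- if (n < length(tree$tip.label)) prune_to_taxa(tree, species) else tree
  ord <- match(tr$tip.label, species)
  X <- X[ord, , drop = FALSE]; y <- y[ord]; species <- species[ord]

  s <- ape::vcv(tr)   # shared depths
  fits <- list(BM = .pgls_one(X, y, s, "BM"))
  if (structure != "BM") {
    fits$OU <- .pgls_one(X, y, s, "OU")
  }
  if (structure == "auto") {
    aw <- akaike_weights(vapply(fits, `[[`, 0, "loglik"),
                         vapply(fits, `[[`, 0L, "k"), n,
                         criterion = criterion)
    for (i in seq_along(fits)) {
      fits[[i]]$criterion <- aw$criterion[i]
      fits[[i]]$weight <- aw$weights[i]
    }
    # >= : ties go to BM, which is listed first
    chosen <- if (aw$weights[1L] >= aw$weights[2L]) "BM" else "OU"
  } else {
    chosen <- structure
    aw <- akaike_weights(fits[[chosen]]$loglik, fits[[chosen]]$k, n,
                         criterion = criterion)
    fits[[chosen]]$criterion <- aw$criterion
    fits[[chosen]]$weight <- 1
  }
  out <- fits[[chosen]]
  names(out$residuals) <- names(out$fitted) <- species
  out$structure <- chosen
  out$fits <- fits
  out$n <- n
  out$species <- species
  out$formula <- formula
  out$tree <- tr
  out$call <- match.call()
  class(out) <- "pgls"
  out
}

# One GLS fit for a fixed correlation family; the scale is profiled out.
# `s` is the matrix of shared root-to-MRCA depths among tips.
.pgls_one <- function(X, y, s, family) {
  n <- length(y); p <- ncol(X)
  T_depth <- max(diag(s))
  gls_at <- function(M) {
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    Miy <- backsolve(R, forwardsolve(t(R), y))
    MiX <- backsolve(R, forwardsolve(t(R), X))
    XtMiX <- crossprod(X, MiX)
    qr_ok <- qr(XtMiX)
    if (qr_ok$rank < p) {
      stop("singular design under GLS weighting; collinear columns: ",
           paste(colnames(X)[qr_ok$pivot[(qr_ok$rank + 1L):p]],
                 collapse = ", "))
    }
    beta <- solve(XtMiX, crossprod(X, Miy))
    r <- y - as.vector(X %*% beta)
    Mir <- backsolve(R, forwardsolve(t(R), r))
    rss <- sum(r * Mir)
    g <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(g) +
                    2 * sum(log(diag(R))) + n)
    list(beta = as.vector(beta), XtMiX = XtMiX, resid = r,
         rss = rss, g = g, loglik = ll)
  }
  if (family == "BM") {
    f <- gls_at(s)
    params <- list(sigma2 = f$g)
    k <- p + 1L
  } else {
    M_of <- function(la) {
      a <- exp(la)
      exp(-2 * a * (T_depth - s)) * (1 - exp(-2 * a * s))
    }
    obj <- function(la) {
      f <- gls_at(M_of(la))
      if (is.null(f)) return(1e10)
      -f$loglik
    }
    starts <- list(c(-10, -2), c(-4, 4), c(2, 10))
    best <- NULL
    for (b in starts) {
      o <- stats::optimize(obj, b, tol = 1e-8)
      if (is.null(best) || o$objective < best$objective) best <- o
    }
    la <- best$minimum
    f <- gls_at(M_of(la))
    a <- exp(la)
    params <- list(sigma2 = 2 * a * f$g, alpha = a)
    k <- p + 2L
  }
  se <- sqrt(diag(solve(f$XtMiX)) * f$rss / (n - p))
  tval <- f$beta / se
  pval <- 2 * stats::pt(-abs(tval), n - p)
  names(f$beta) <- names(se) <- names(tval) <- names(pval) <- colnames(X)
  list(coefficients = f$beta, se = se, t = tval, p.value = pval,
       residuals = f$resid, fitted = y - f$resid,
       loglik = f$loglik, k = k, df.residual = n - p,
       sigma2 = params$sigma2, alpha = params$alpha)
}

#' @export
print.pgls <- function(x, ...) {
  cat("PGLS fit (", x$structure, " error structure), n = ", x$n, "\n",
      sep = "")
  print(round(cbind(Estimate = x$coefficients, SE = x$se,
                    t = x$t, p = x$p.value), 5))
  if (length(x$fits) > 1L) {
    w <- vapply(x$fits, `[[`, 0, "weight")
    cat("Akaike weights: ",
        paste(sprintf("%s = %.3f", names(w), w), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.pgls <- function(object, ...) {
  object
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
residuals.pgls <- function(object, ...) object$residuals

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
logLik.pgls <- function(object, ...) {
  structure(object$loglik, df = object$fits[[object$structure]]$k,
            class = "logLik")
}

#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  X <- stats::model.matrix(stats::delete.response(stats::terms(object$formula)),
                           as.data.frame(newdata))
  as.vector(X %*% object$coefficients)
}

#' Akaike weights across candidate models
#'
#' Computes small-sample AICc = -2 logL + 2k + 2k(k+1)/(n-k-1) for each
#' model and the normalized weights w_i proportional to exp(-Delta_i / 2).
#' When `n <= max(k) + 1` the correction term is undefined and the function
#' falls back to plain AIC with a warning flag in the result.
#'
#' @param loglik Numeric vector of maximized log-likelihoods.
#' @param k Integer vector of parameter counts (same length).
#' @param n Common sample size.
#' @param criterion `"AICc"` (default) or `"AIC"`.
#' @return List with `criterion` (values), `delta`, `weights`, `used`
#'   (criterion actually applied), and `fallback` flag.
#' @export
akaike_weights <- function(loglik, k, n, criterion = c("AICc", "AIC")) {
  criterion <- match.arg(criterion)
  stopifnot(length(loglik) == length(k))
  fallback <- FALSE
  if (criterion == "AICc" && n <= max(k) + 1) {
    warning("n <= k + 1: falling back to AIC")
    criterion <- "AIC"
    fallback <- TRUE
  }
  ic <- -2 * loglik + 2 * k
  if (criterion == "AICc") ic <- ic + 2 * k * (k + 1) / (n - k - 1)
  delta <- ic - min(ic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  names(ic) <- names(delta) <- names(w) <- names(loglik)
  list(criterion = ic, delta = delta, weights = w, used = criterion,
       fallback = fallback)
}

#' Phylogenetic residuals (body-mass correction)
#'
#' Residuals of a PGLS regression of `y` on `x`, the standard device for
#' body-mass-corrected trait values: residual eye mass (rEM) is the residual
#' of species-mean log10(eye mass) regressed on log10(body mass). The
#' V-inverse-weighted mean of the residuals is zero by the GLS normal
#' equations.
#'
#' @param tree A `"phylo"` tree.
#' @param y,x Named numeric vectors (names = species).
#' @param structure Error structure passed to [pgls_fit()].
#' @return Named residual vector with the `"pgls"` fit as attribute `fit`.
#' @export
phylo_residuals <- function(tree, y, x, structure = "auto") {
  common <- intersect(names(y)[!is.na(y)], names(x)[!is.na(x)])
  d <- data.frame(y = y[common], x = x[common], row.names = common)
  fit <- pgls_fit(y ~ x, d, tree, structure = structure)
  r <- stats::residuals(fit)
  attr(r, "fit") <- fit
  r
}
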