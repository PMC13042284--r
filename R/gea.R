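#' Greedy correlation pruning of environmental variables
#'
#' Scans variables in the supplied column order (the priority order) and
#' drops any whose absolute Pearson correlation with an already-retained
#' variable reaches \code{r_max}. Constant columns are dropped with a
#' warning (their correlation is undefined).
#'
#' @param env data frame of numeric variables, one row per sample.
#' @param r_max correlation threshold (a pair at or above it conflicts).
#' @return the pruned data frame, with attributes \code{dropped} (named list
#'   of conflicting retained variables) recording the decisions.
#' @export
prune_env <- function(env, r_max = 0.7) {
  num <- vapply(env, is.numeric, TRUE)
  env_num <- env[num]
  if (ncol(env_num) < 2) stop("need at least 2 numeric variables")
  keep <- character()
  dropped <- list()
  for (v in names(env_num)) {
    x <- env_num[[v]]
    if (stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      warning("constant column dropped: ", v)
      dropped[[v]] <- "constant"
      next
    }
    conflict <- NULL
    for (k in keep) {
      r <- stats::cor(x, env_num[[k]], use = "pairwise.complete.obs")
      if (is.finite(r) && abs(r) >= r_max) { conflict <- k; break }
    }
    if (is.null(conflict)) keep <- c(keep, v) else dropped[[v]] <- conflict
  }
  out <- env_num[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Slope and aspect from a DEM grid
#'
#' Eight-neighbour finite differences with Horn's weights on an elevation
#' matrix whose first row is the northern edge and whose columns run west to
#' east. Slope is \code{atan(|grad z|)} in degrees; aspect is the compass
#' bearing of the downslope direction in degrees \[0, 360) (0 = north,
#' 90 = east). Flat cells and cells whose 3x3 neighbourhood contains a
#' non-finite value get \code{NA} aspect (and \code{NA} slope for the
#' latter); the one-cell border is \code{NA}.
#'
#' @param dem numeric elevation matrix (at least 3x3).
#' @param cellsize grid spacing in the same units as elevation.
#' @return list of matrices \code{slope} and \code{aspect} (degrees).
#' @export
slope_aspect <- function(dem, cellsize = 1) {
  dem <- as.matrix(dem)
  if (nrow(dem) < 3 || ncol(dem) < 3) stop("DEM must be at least 3x3")
  nr <- nrow(dem); nc <- ncol(dem)
  slope <- aspect <- matrix(NA_real_, nr, nc)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      z <- dem[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (any(!is.finite(z))) next
      gx <- ((z[1, 3] + 2 * z[2, 3] + z[3, 3]) -
             (z[1, 1] + 2 * z[2, 1] + z[3, 1])) / (8 * cellsize)
      gy <- ((z[1, 1] + 2 * z[1, 2] + z[1, 3]) -
             (z[3, 1] + 2 * z[3, 2] + z[3, 3])) / (8 * cellsize)
      slope[i, j] <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
      if (gx != 0 || gy != 0) {
        aspect[i, j] <- (atan2(-gx, -gy) * 180 / pi) %% 360
      }
    }
  }
  list(slope = slope, aspect = aspect)
}

#' Snow-melt day from daily snow-cover series
#'
#' Per snow year, the melt day is the first day in the second half of the
#' year for which at least 15 of the previous 30 days were snow-free; the
#' returned value is the mean over years. Years with no qualifying day are
#' skipped with a warning.
#'
#' @param series 0/1 snow flags: a vector (one year) or a matrix with one
#'   year per row; at least 300 days per year.
#' @return mean melt day (day-of-year index), or \code{NA} if no year
#'   qualifies.
#' @export
snow_melt_day <- function(series) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  if (ncol(series) < 300) stop("need at least 300 days per snow year")
  melt_one <- function(s) {
    n <- length(s)
    start <- floor(n / 2) + 1L
    for (d in start:n) {
      if (sum(s[(d - 30):(d - 1)] == 0) >= 15) return(d)
    }
    NA_integer_
  }
  melts <- apply(series, 1, melt_one)
  if (any(is.na(melts))) {
    warning(sum(is.na(melts)), " year(s) with no qualifying melt day skipped")
  }
  if (all(is.na(melts))) return(NA_real_)
  mean(melts, na.rm = TRUE)
}

#' Neighbourhood smoothing of a melt-day grid
#'
#' Replaces each pixel by the mean of itself and its up-to-8 neighbours
#' (NA-aware), the smoothing applied before averaging melt dates over years
#' at a sampling location.
#'
#' @param grid numeric matrix.
#' @return smoothed matrix of the same dimension.
#' @export
smooth_neighbors <- function(grid) {
  grid <- as.matrix(grid)
  nr <- nrow(grid); nc <- ncol(grid)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- grid[max(1, i - 1):min(nr, i + 1), max(1, j - 1):min(nc, j + 1)]
      out[i, j] <- mean(block, na.rm = TRUE)
    }
  }
  out
}

#' Leading redundancy-analysis axis for a single response
#'
#' With a single response variable the constrained ordination reduces to an
#' ordinary least-squares regression of the hybrid index on the standardised
#' environmental variables: the RDA1 score is the centred fitted value, the
#' loadings are the standardised coefficients, and the proportion of
#' hybrid-index variance explained is the regression R-squared. Rows with
#' missing values are dropped; exactly collinear variables are dropped with
#' a warning.
#'
#' @param h hybrid-index vector.
#' @param env pruned environment data frame (numeric columns used).
#' @return list with \code{scores} (centred, \code{NA} for dropped rows),
#'   \code{loadings} (standardised coefficients), \code{r_squared},
#'   \code{n} rows used.
#' @export
fit_rda1 <- function(h, env) {
  num <- vapply(env, is.numeric, TRUE)
  x <- as.matrix(env[num])
  if (length(h) != nrow(x)) stop("h and env must have matching rows")
  ok <- stats::complete.cases(x) & !is.na(h)
  xs <- scale(x[ok, , drop = FALSE])
  fit <- stats::lm.fit(cbind(1, xs), h[ok])
  aliased <- is.na(fit$coefficients)
  if (any(aliased[-1])) {
    warning("collinear variables dropped: ",
            paste(colnames(xs)[aliased[-1]], collapse = ", "))
  }
  fitted <- fit$fitted.values
  scores <- rep(NA_real_, length(h))
  scores[ok] <- fitted - mean(fitted)
  r2 <- sum((fitted - mean(h[ok]))^2) / sum((h[ok] - mean(h[ok]))^2)
  loadings <- fit$coefficients[-1]
  names(loadings) <- colnames(xs)
  list(scores = scores, loadings = loadings, r_squared = r2, n = sum(ok))
}

# ridge-stabilised binomial-logit fit (dosage out of 2 trials); the tiny
# penalty (never on the intercept) keeps separated loci finite and the fit
# deterministic. Returns the unpenalised log-likelihood at the optimum.
ridge_logit <- function(X, g, lambda = 1e-6, maxit = 200, tol = 1e-10) {
  X <- as.matrix(X)
  pen <- rep(lambda, ncol(X)); pen[1] <- 0
  beta <- numeric(ncol(X))
  log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  ll_pen <- function(b) {
    eta <- drop(X %*% b)
    sum(g * eta - 2 * log1pexp(eta)) - sum(pen * b^2) / 2
  }
  cur <- ll_pen(beta)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- 2 * mu * (1 - mu)
    score <- drop(crossprod(X, g - 2 * mu)) - pen * beta
    H <- crossprod(X * w, X) + diag(pen + 1e-12, ncol(X))
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    new <- ll_pen(beta + step)
    halve <- 0
    while (new < cur && halve < 30) {
      step <- step / 2
      new <- ll_pen(beta + step)
      halve <- halve + 1
    }
    beta <- beta + step
    if (new - cur < tol * (abs(cur) + 1)) { cur <- new; conv <- TRUE; break }
    cur <- new
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
  list(beta = beta, loglik = sum(stats::dbinom(g, 2, mu, log = TRUE)),
       converged = conv)
}

#' Per-SNP genotype-environment association likelihood-ratio test
#'
#' At each locus, allele dosage is modelled as binomial (two trials per
#' individual, logit link) on the composite environmental predictor. The
#' plain variant compares an intercept-only null (the SNP frequency
#' predicted by its mean alone) to intercept + predictor (1 df). The
#' structure-corrected variant adds the leading genotype PCA axis: null is
#' intercept + PC1, alternative adds the predictor and its interaction with
#' PC1 (2 df). P-values come from the chi-square upper tail of twice the
#' log-likelihood difference. Fits are ridge-stabilised (penalty 1e-6) so
#' separated loci remain finite; the statistic is invariant to affine
#' rescaling of the predictor.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param predictor per-individual composite predictor (e.g. RDA1 scores).
#' @param covariate optional structure covariate (e.g. PC1); supplying it
#'   selects the corrected variant.
#' @param interaction include the predictor-by-covariate interaction in the
#'   corrected variant (default \code{TRUE}, df = 2; \code{FALSE} gives a
#'   1-df corrected test).
#' @param min_n minimum called genotypes per locus.
#' @return data frame per locus: \code{lrt}, \code{df}, \code{p},
#'   \code{converged}, \code{variant}.
#' @export
gea_lrt <- function(geno, predictor, covariate = NULL, interaction = TRUE,
                    min_n = 20) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (length(predictor) != nrow(geno$dosage)) {
    stop("predictor must have one value per individual")
  }
  if (any(!is.finite(predictor[!is.na(predictor)]))) stop("predictor must be finite")
  corrected <- !is.null(covariate)
  variant <- if (corrected) "structure_corrected" else "plain"
  L <- ncol(geno$dosage)
  out <- data.frame(lrt = rep(NA_real_, L), df = NA_integer_, p = NA_real_,
                    converged = NA, variant = variant)
  for (l in seq_len(L)) {
    g <- geno$dosage[, l]
    ok <- !is.na(g) & !is.na(predictor)
    if (corrected) ok <- ok & !is.na(covariate)
    if (sum(ok) < min_n) next
    gg <- g[ok]; pr <- predictor[ok]
    if (corrected) {
      cv <- covariate[ok]
      X0 <- cbind(1, cv)
      X1 <- if (interaction) cbind(1, cv, pr, pr * cv) else cbind(1, cv, pr)
    } else {
      X0 <- matrix(1, length(gg), 1)
      X1 <- cbind(1, pr)
    }
    f0 <- ridge_logit(X0, gg)
    f1 <- ridge_logit(X1, gg)
    stat <- max(0, 2 * (f1$loglik - f0$loglik))
    df <- ncol(X1) - ncol(X0)
    out$lrt[l] <- stat
    out$df[l] <- df
    out$converged[l] <- f0$converged && f1$converged
    if (f0$converged && f1$converged) {
      out$p[l] <- stats::pchisq(stat, df, lower.tail = FALSE)
    }
  }
  out
}

#' Empirical-percentile GEA outliers
#'
#' Flags loci whose p-value is at or below the empirical
#' \code{percentile}-th percentile of the defined p-values; ties at the
#' cutoff are all included, so the set can exceed the nominal fraction.
#'
#' @param p per-locus p-values (\code{NA} ignored).
#' @param percentile percentile in (0, 100), default 1.
#' @return logical vector aligned with \code{p}.
#' @export
gea_outliers <- function(p, percentile = 1.0) {
  defined <- which(is.finite(p))
  if (length(defined) < 100) stop("need at least 100 defined p-values")
  k <- ceiling(percentile / 100 * length(defined))
  cutoff <- sort(p[defined])[k]
  !is.na(p) & p <= cutoff
}
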