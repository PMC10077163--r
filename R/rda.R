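# Redundancy analysis of log-transformed group abundances against
# standardized environmental predictors, plus a permutation test.

.rda_prepare <- function(response, predictors, warn = TRUE) {
  Yraw <- as.matrix(response)
  X <- as.matrix(predictors)
  if (nrow(Yraw) != nrow(X)) stop("response and predictors must share stations")
  n <- nrow(Yraw)
  if (n < 2) stop("need at least 2 stations")
  if (any(Yraw < 0)) stop("abundances must be >= 0")
  if (warn && n < ncol(X) + 2) {
    warning("fewer than p + 2 stations; RDA will be saturated or unstable")
  }
  Y <- scale(log1p(Yraw), center = TRUE, scale = FALSE)

  # drop constant predictors, then prune perfect collinearity: repeatedly
  # drop the later column of the most correlated pair until full rank
  keep <- which(apply(X, 2, stats::sd) > 0)
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
  X <- X[, keep, drop = FALSE]
  repeat {
    if (!ncol(X)) stop("no usable predictors")
    Z <- scale(X)
    if (qr(Z)$rank == ncol(Z)) break
    cc <- abs(stats::cor(Z)); diag(cc) <- 0
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    drop_j <- max(ij)
    dropped <- c(dropped, colnames(X)[drop_j])
    X <- X[, -drop_j, drop = FALSE]
  }
  if (warn && length(dropped)) {
    warning("dropped collinear/constant predictor(s): ",
            paste(dropped, collapse = ", "))
  }
  list(Y = Y, Z = scale(X), n = n, dropped = dropped)
}

#' Redundancy analysis (constrained ordination)
#'
#' Fits an RDA of a station x group abundance matrix on a station x
#' environment matrix. The response is `ln(x + 1)`-transformed and
#' column-centered; predictors are standardized to zero mean and unit
#' variance (constant columns are dropped, and perfectly collinear
#' predictors are pruned by repeatedly dropping the later column of the
#' most correlated pair, with a warning). Constrained axes are the
#' singular axes of the fitted values `Yhat = Z (Z'Z)^-1 Z' Y`;
#' unconstrained axes those of the residuals. Eigenvalues are singular
#' values squared over `n - 1`, so constrained plus unconstrained
#' eigenvalues sum to the total variance of the transformed response.
#'
#' Score conventions (fixed): site scores are the projections of the
#' fitted values on the constrained axes (`U D`); species scores are the
#' response loadings scaled by axis standard deviation
#' (`V diag(d) / sqrt(n - 1)`, i.e. covariances with the unit-variance
#' axes); biplot scores are correlations of the standardized predictors
#' with the site scores. Axis signs are fixed so the largest-magnitude
#' species loading on each axis is positive.
#'
#' @param response Station x group (or taxon) abundance matrix, raw scale.
#' @param predictors Station x environment matrix, same station order.
#' @return Object of class `rda_result`: `constrained_eigenvalues`,
#'   `unconstrained_eigenvalues`, `explained_fraction`, `site_scores`,
#'   `species_scores`, `biplot_scores`, `dropped_predictors`,
#'   `total_variance`.
#' @export
rda_fit <- function(response, predictors) {
  prep <- .rda_prepare(response, predictors)
  Y <- prep$Y; Z <- prep$Z; n <- prep$n

  B <- solve(crossprod(Z), crossprod(Z, Y))
  Yhat <- Z %*% B
  Yres <- Y - Yhat

  sv <- svd(Yhat)
  tol <- max(sv$d) * 1e-9
  r <- sum(sv$d > tol)
  if (r == 0) r <- 0L
  lambda <- sv$d^2 / (n - 1)
  resid_sv <- svd(Yres)$d
  resid_lambda <- resid_sv[resid_sv > max(resid_sv[1], 1e-300) * 1e-9]^2 / (n - 1)

  total_ss <- sum(Y^2)
  explained <- if (total_ss > 0) sum(Yhat^2) / total_ss else 0

  site <- species <- biplot <- NULL
  if (r > 0) {
    U <- sv$u[, seq_len(r), drop = FALSE]
    V <- sv$v[, seq_len(r), drop = FALSE]
    d <- sv$d[seq_len(r)]
    flip <- vapply(seq_len(r), function(a) {
      j <- which.max(abs(V[, a]))
      if (V[j, a] < 0) -1 else 1
    }, numeric(1))
    U <- sweep(U, 2, flip, "*")
    V <- sweep(V, 2, flip, "*")
    axes <- paste0("RDA", seq_len(r))
    site <- U %*% diag(d, r)
    dimnames(site) <- list(rownames(Z), axes)
    species <- V %*% diag(d / sqrt(n - 1), r)
    dimnames(species) <- list(colnames(Y), axes)
    biplot <- stats::cor(Z, site)
    dimnames(biplot) <- list(colnames(Z), axes)
  }

  structure(list(constrained_eigenvalues = lambda[seq_len(r)],
                 unconstrained_eigenvalues = resid_lambda,
                 explained_fraction = explained,
                 site_scores = site, species_scores = species,
                 biplot_scores = biplot,
                 dropped_predictors = prep$dropped,
                 total_variance = total_ss / (n - 1)),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf("rda_result: %d constrained axes, %.1f%% variance explained\n",
              length(x$constrained_eigenvalues), 100 * x$explained_fraction))
  invisible(x)
}

#' Permutation test for the RDA explained fraction
#'
#' Permutes station rows of the response, refits, and compares explained
#' fractions: `p = (1 + #{perm >= observed}) / (1 + n_perm)`.
#'
#' @param response,predictors As in [rda_fit()].
#' @param n_perm Number of permutations (>= 1; >= 99 recommended).
#' @param seed Integer seed; identical seeds give identical p values.
#' @return List: `p_value`, `observed` (explained fraction), `n_perm`.
#' @export
rda_permutation_test <- function(response, predictors, n_perm = 999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  prep <- .rda_prepare(response, predictors, warn = FALSE)
  Y <- prep$Y; Z <- prep$Z; n <- prep$n
  H <- Z %*% solve(crossprod(Z), t(Z))
  total <- sum(Y^2)
  stat <- function(Yp) if (total > 0) sum((H %*% Yp)^2) / sum(Yp^2) else 0
  observed <- stat(Y)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    Yp <- scale(Yp, center = TRUE, scale = FALSE)
    if (stat(Yp) >= observed - 1e-12) exceed <- exceed + 1L
  }
  list(p_value = (1 + exceed) / (1 + n_perm), observed = observed,
       n_perm = as.integer(n_perm))
}
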