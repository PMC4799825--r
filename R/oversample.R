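# Minority-class balancing by correlated Gaussian noise: normality
# screening, standard-normal generation, triangular correlation
# induction, and k-scaled restoration of native means/SDs.

#' Kolmogorov-Smirnov normality screen
#'
#' Screens each variable for compatibility with a normal distribution
#' using a one-sample Kolmogorov-Smirnov test against a normal with the
#' variable's own sample mean and SD. The Gaussian-noise oversampler
#' assumes (approximately) normal marginals; variables failing the
#' screen are reported with a warning but do not abort generation.
#'
#' @param x A numeric matrix or data frame (observations in rows) or a
#'   named list of numeric vectors.
#' @param alpha Significance level; a variable passes iff its KS p-value
#'   is >= `alpha`. Default 0.01.
#' @return A data frame with columns `variable`, `n`, `statistic`,
#'   `p_value`, `pass`.
#' @export
normality_screen <- function(x, alpha = 0.01) {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (is.data.frame(x)) x <- as.list(x)
  if (!is.list(x) || length(x) == 0L)
    stop("`x` must be a matrix, data frame or list of numeric vectors",
         call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  nm <- names(x) %||% paste0("V", seq_along(x))
  res <- lapply(seq_along(x), function(i) {
    v <- x[[i]][is.finite(x[[i]])]
    if (length(v) < 5L)
      stop(sprintf("variable '%s' has %d observations; at least 5 required",
                   nm[i], length(v)), call. = FALSE)
    ks <- suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))
    data.frame(variable = nm[i], n = length(v),
               statistic = unname(ks$statistic), p_value = ks$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$pass <- out$p_value >= alpha
  if (any(!out$pass))
    warning(sprintf("normality screen failed at alpha = %g for: %s",
                    alpha, paste(out$variable[!out$pass], collapse = ", ")),
            call. = FALSE)
  out
}

#' Induce a target correlation between two standard-score vectors
#'
#' Given standard scores `u`, `v` (zero mean, unit variance) the pair
#' `u' = u * sqrt(1 - rho^2) + v * rho`, `v' = v` again has zero mean and
#' unit variance, with correlation `rho` when `u` and `v` are
#' independent. This is the two-variable triangular correlation
#' induction that the multivariate generator generalises.
#'
#' @param u,v Numeric vectors of equal length.
#' @param rho Target correlation in \[-1, 1\].
#' @return A list with elements `u_prime` and `v_prime` (`v` unchanged).
#' @export
#' @examples
#' z <- correlate_pair(rnorm(1e4), rnorm(1e4), 0.7)
#' cor(z$u_prime, z$v_prime)  # ~0.7
correlate_pair <- function(u, v, rho) {
  if (length(u) != length(v))
    stop("`u` and `v` must have the same length", call. = FALSE)
  assert_scalar_num(rho, "rho")
  if (abs(rho) > 1) stop("`rho` must lie in [-1, 1]", call. = FALSE)
  list(u_prime = u * sqrt(1 - rho^2) + v * rho, v_prime = v)
}

#' Map standard scores to native units
#'
#' Restores native location and scale: `mu + k * sigma * z`. The factor
#' `k` is the proportionality constant of the Gaussian noise; `k = 1`
#' reproduces the estimating sample's SD, smaller `k` shrinks the
#' synthetic cloud around the class means.
#'
#' @param z Numeric vector of standard scores.
#' @param mu Native mean.
#' @param sigma Native SD (> 0).
#' @param k Noise proportionality factor (> 0), default 1.
#' @return Numeric vector in native units.
#' @export
scale_shift <- function(z, mu, sigma, k = 1) {
  assert_scalar_num(mu, "mu")
  assert_scalar_num(sigma, "sigma", positive = TRUE)
  assert_scalar_num(k, "k", positive = TRUE)
  mu + k * sigma * z
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Correlation matrices estimated from few observations (or assembled
#' from pairwise targets) can be rank-deficient or indefinite. Eigen
#' decomposition, clipping of eigenvalues below `eps`, reconstruction
#' and renormalisation to unit diagonal yield a valid nearby matrix.
#'
#' @param r Symmetric matrix with unit diagonal.
#' @param eps Eigenvalue floor, default `1e-6`.
#' @return A positive-definite correlation matrix.
#' @export
nearest_corr <- function(r, eps = 1e-6) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8)
    stop("`r` must be a symmetric square matrix", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8))
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  e <- eigen((r + t(r)) / 2, symmetric = TRUE)
  if (min(e$values) >= eps) return(r)
  v <- pmax(e$values, eps)
  out <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(r)
  out
}

#' Induce a full correlation structure on independent standard normals
#'
#' Multivariate generalisation of [correlate_pair()]: a triangular
#' (Cholesky) factor of the (repaired) target correlation matrix mixes
#' the columns of `z`. For two variables and the canonical order
#' (`v` first, `u` second) this reduces exactly to the pairwise rule.
#'
#' @param z Numeric matrix of independent standard scores, one column
#'   per variable.
#' @param r Target correlation matrix, `ncol(z)` square.
#' @return Matrix of the same shape as `z` whose columns have unit
#'   variance and correlation structure `r` in expectation.
#' @export
induce_correlations <- function(z, r) {
  z <- as.matrix(z)
  r <- as.matrix(r)
  if (ncol(z) != ncol(r))
    stop("`z` must have one column per variable of `r`", call. = FALSE)
  rr <- nearest_corr(r)
  out <- z %*% chol(rr)   # chol() upper: cov(z %*% U) = U'U = rr
  colnames(out) <- colnames(r)
  out
}

#' Number of synthetic sessions needed to balance the classes
#'
#' @param n_majority,n_minority Class counts, `n_majority >= n_minority`.
#' @return `n_majority - n_minority`.
#' @export
#' @examples
#' balance_count(183, 17)  # 166
balance_count <- function(n_majority, n_minority) {
  assert_scalar_num(n_majority, "n_majority")
  assert_scalar_num(n_minority, "n_minority")
  if (n_minority < 0 || n_majority < n_minority)
    stop("need `n_majority` >= `n_minority` >= 0", call. = FALSE)
  as.integer(n_majority - n_minority)
}

#' Generate synthetic symptomatic sessions by correlated Gaussian noise
#'
#' Estimates per-variable means/SDs and the full pairwise correlation
#' matrix of the symptomatic sample (all vitals over the T0..T8 grid
#' plus prescription fields), draws independent standard normals,
#' induces the estimated correlations through a triangular
#' factorisation, and restores native units with SD scaled by `k`.
#' Onset timepoints for the synthetic sessions are resampled from the
#' empirical onset distribution of the estimating sample.
#'
#' @param symptomatic A cohort data frame (see [simulate_cohort()])
#'   containing the symptomatic sessions to emulate; at least 3 rows.
#' @param n_new Number of synthetic sessions to generate.
#' @param k Noise proportionality factor, default 1.
#' @param seed Integer seed; generation is byte-reproducible given it.
#' @param screen Run [normality_screen()] on the estimating sample and
#'   warn about failures (default TRUE).
#' @return A cohort data frame of `n_new` rows with `is_synthetic =
#'   TRUE` and `symptomatic = TRUE`; session ids never collide with the
#'   estimating sample's.
#' @export
oversample_sessions <- function(symptomatic, n_new, k = 1, seed = 1,
                                screen = TRUE) {
  symptomatic <- as.data.frame(symptomatic)
  if (!all(symptomatic$symptomatic))
    stop("`symptomatic` must contain symptomatic sessions only", call. = FALSE)
  if (nrow(symptomatic) < 3L)
    stop("at least 3 symptomatic sessions are required to estimate moments",
         call. = FALSE)
  assert_scalar_num(n_new, "n_new")
  if (n_new < 0) stop("`n_new` must be >= 0", call. = FALSE)
  assert_scalar_num(k, "k", positive = TRUE)
  vars <- c(vital_cols(), prescription_cols())
  missing <- setdiff(vars, names(symptomatic))
  if (length(missing))
    stop("estimating sample lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  x <- as.matrix(symptomatic[, vars])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("estimating sample contains missing values", call. = FALSE)
  if (screen && nrow(x) >= 5L) normality_screen(as.data.frame(x))
  mu <- colMeans(x)
  sigma <- apply(x, 2, stats::sd)
  const <- sigma < 1e-12          # constant columns carry no correlation
  r <- diag(length(vars))
  dimnames(r) <- list(vars, vars)
  if (any(!const)) {
    r[!const, !const] <- stats::cor(x[, !const, drop = FALSE])
  }
  out <- with_seed(seed, {
    if (n_new == 0L) {
      matrix(numeric(0), nrow = 0, ncol = length(vars),
             dimnames = list(NULL, vars))
    } else {
      z <- matrix(stats::rnorm(n_new * length(vars)), nrow = n_new)
      zc <- induce_correlations(z, r)
      sweep(sweep(zc, 2, ifelse(const, 0, k * sigma), `*`), 2, mu, `+`)
    }
  })
  # Gaussian tails can cross zero at large k; session records require
  # strictly positive vitals and a nonnegative prescription, so clamp
  floors <- ifelse(vars == "hourly_weight_loss", 0.01, 1)
  out <- pmax(out, matrix(floors, nrow(out), length(vars), byrow = TRUE))
  synth <- as.data.frame(out)
  n_new <- as.integer(n_new)
  onset_pool <- symptomatic$onset_index
  synth_meta <- data.frame(
    patient_id = rep("synthetic", n_new),
    session_id = sprintf("syn_%05d", seq_len(n_new)),
    symptomatic = rep(TRUE, n_new),
    onset_index = if (n_new > 0)
      with_seed(derive_seed(seed, 1L),
                sample(onset_pool, n_new, replace = TRUE))
      else integer(0),
    is_synthetic = rep(TRUE, n_new),
    stringsAsFactors = FALSE
  )
  res <- cbind(synth_meta, synth)
  class(res) <- c("hd_cohort", "data.frame")
  res
}
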