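#' Exponentially decreasing retention fraction (EDF)
#'
#' The forced coarse-screening schedule used by CARS: at iteration i of N,
#' the fraction of the p original wavelengths retained is
#' \deqn{r_i = a e^{-k i}, \quad a = (p/2)^{1/(N-1)}, \quad
#'       k = \ln(p/2)/(N-1)} so that \eqn{r_1 = 1} (all p wavelengths) and
#' \eqn{r_N = 2/p} (two wavelengths). The retained count is
#' `round(r_i * p)`, floored at 2.
#'
#' @param i iteration index, `1 <= i <= N`.
#' @param N total number of iterations, `>= 2`.
#' @param p number of original wavelengths, `>= 3`.
#' @return The fraction `r_i`, with attribute `count` = `max(2, round(r_i * p))`.
#' @export
edf_ratio <- function(i, N, p) {
  if (N < 2) stop("N must be >= 2")
  if (p < 3) stop("p must be >= 3")
  if (any(i < 1 | i > N)) stop("i must lie in [1, N]")
  a <- (p / 2)^(1 / (N - 1))
  k <- log(p / 2) / (N - 1)
  r <- a * exp(-k * i)
  structure(r, count = pmax(2L, as.integer(round(r * p))))
}

#' Competitive adaptive reweighted sampling (CARS) configuration
#'
#' @param n_iterations Monte-Carlo iterations N (default 50).
#' @param mc_fraction fraction of calibration samples drawn per iteration
#'   (default 0.8, without replacement).
#' @param max_pls_components cap on the PLS latent-variable count (default 10).
#' @param cv_folds folds for the RMSECV scoring of each subset (default 5).
#' @param seed integer seed; the whole run is a pure function of data + seed.
#' @param ars one of `"weighted"` (classic adaptive reweighted sampling:
#'   weighted draws with replacement, unique hits retained) or `"top"`
#'   (deterministic top-|coefficient| alternative).
#' @return A `cars_config` list.
#' @export
cars_config <- function(n_iterations = 50L, mc_fraction = 0.8,
                        max_pls_components = 10L, cv_folds = 5L, seed = 1L,
                        ars = c("weighted", "top")) {
  if (n_iterations < 3L) stop("n_iterations must be >= 3")
  if (mc_fraction <= 0 || mc_fraction >= 1) stop("mc_fraction must be in (0,1)")
  structure(list(n_iterations = as.integer(n_iterations),
                 mc_fraction = mc_fraction,
                 max_pls_components = as.integer(max_pls_components),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed),
                 ars = match.arg(ars)),
            class = "cars_config")
}

#' Select effective wavelengths by CARS
#'
#' Each iteration (1) draws a Monte-Carlo subset of the calibration samples,
#' (2) fits a PLS model on the currently retained wavelengths, (3) applies
#' the exponentially decreasing function to force-retain the top wavelengths
#' ranked by absolute regression coefficient, (4) runs adaptive reweighted
#' sampling — draws with replacement, weights proportional to |coefficient|,
#' the unique hits survive — and (5) scores the surviving subset by k-fold
#' RMSECV on the full calibration set. The subset with minimum RMSECV over
#' all iterations is returned (ties toward the earliest iteration, i.e. the
#' larger subset).
#'
#' The PLS component count is chosen once, on the full calibration set by
#' cross-validation, before iterating, and is capped per-fit by subset size.
#'
#' @param x `spectrum_set` (or samples x bands matrix) of calibration rows.
#' @param y reference values, one per calibration row; must have variance.
#' @param cfg a [cars_config()].
#' @return A `selection_result`: list with `selected_indices` (sorted,
#'   1-based), `selected_wavelengths`, `per_iteration` (data.frame of subset
#'   size and RMSECV), `chosen_iteration`, `method = "CARS"`, `n_components`.
#' @export
cars_select <- function(x, y, cfg = cars_config()) {
  wl <- if (inherits(x, "spectrum_set")) x$wavelengths else seq_len(ncol(x))
  X <- if (inherits(x, "spectrum_set")) x$X else as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (stats::var(y) <= 0) stop("reference values have zero variance")
  if (n < 2L * cfg$cv_folds) stop("need at least 2 * cv_folds samples")
  if (p < 3L) stop("need at least 3 bands")

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)

  A0 <- as.integer(plsr_choose_components(
    X, y, Amax = min(cfg$max_pls_components, p, n - 2L),
    folds = cfg$cv_folds, seed = cfg$seed))

  N <- cfg$n_iterations
  n_mc <- max(2L, round(cfg$mc_fraction * n))
  retained <- seq_len(p)
  sizes <- integer(N)
  rmsecv <- numeric(N)
  subsets <- vector("list", N)

  for (i in seq_len(N)) {
    rows <- sample(n, n_mc)
    A_i <- min(A0, length(retained), n_mc - 1L)
    fit <- plsr_fit(X[rows, retained, drop = FALSE], y[rows], A = A_i)
    w <- abs(fit$coefficients)
    # EDF forced reduction (count based on the original p)
    keep_n <- min(length(retained), attr(edf_ratio(i, N, p), "count"))
    ord <- order(w, decreasing = TRUE)
    retained <- retained[ord[seq_len(keep_n)]]
    w <- w[ord[seq_len(keep_n)]]
    # adaptive reweighted sampling among the survivors
    if (cfg$ars == "weighted" && any(w > 0)) {
      hits <- sample(seq_along(retained), size = keep_n, replace = TRUE,
                     prob = w)
      uniq <- sort(unique(hits))
      if (length(uniq) < 2L) uniq <- order(w, decreasing = TRUE)[1:2]
      retained <- sort(retained[uniq])
    } else {
      retained <- sort(retained)
    }
    sizes[i] <- length(retained)
    rmsecv[i] <- pls_cv_rmse(X[, retained, drop = FALSE], y,
                             A = min(A0, length(retained)),
                             folds = cfg$cv_folds, seed = cfg$seed)
    subsets[[i]] <- retained
  }
  best <- which.min(rmsecv)
  structure(list(selected_indices = subsets[[best]],
                 selected_wavelengths = wl[subsets[[best]]],
                 per_iteration = data.frame(iteration = seq_len(N),
                                            subset_size = sizes,
                                            rmsecv = rmsecv),
                 chosen_iteration = best, method = "CARS",
                 n_components = A0),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(x$method, "selection:", length(x$selected_indices), "bands",
      "(chosen iteration", x$chosen_iteration, ")\n")
  invisible(x)
}

#' Successive projections algorithm configuration
#'
#' @param min_vars,max_vars chain-length range to evaluate (defaults 1, 50).
#' @param validation_fraction fraction of rows held out for MLR validation
#'   scoring (default 0.25).
#' @param seed seed for the calibration/validation split.
#' @return A `spa_config` list.
#' @export
spa_config <- function(min_vars = 1L, max_vars = 50L,
                       validation_fraction = 0.25, seed = 1L) {
  if (min_vars > max_vars) stop("min_vars must be <= max_vars")
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("validation_fraction must be in (0, 1)")
  }
  structure(list(min_vars = as.integer(min_vars),
                 max_vars = as.integer(max_vars),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "spa_config")
}

#' One successive-projections step
#'
#' Among the unselected columns of `Xcols`, returns the index whose component
#' orthogonal to the span of the already-selected columns has the largest
#' Euclidean norm; ties break toward the lowest index.
#'
#' @param Xcols numeric matrix whose columns are candidate variables.
#' @param selected non-empty integer vector of already-selected columns.
#' @param tol relative squared-norm tolerance below which a projection
#'   counts as numerically zero (exact collinearity up to round-off).
#' @return The chosen column index, or `NA_integer_` if every remaining
#'   projection is numerically zero (chain exhausted).
#' @export
spa_projection_step <- function(Xcols, selected, tol = 1e-12) {
  Xcols <- as.matrix(Xcols)
  if (!length(selected)) stop("selected must be non-empty")
  candidates <- setdiff(seq_len(ncol(Xcols)), selected)
  if (!length(candidates)) stop("no unselected columns remain")
  Q <- qr.Q(qr(Xcols[, selected, drop = FALSE]))
  Xc <- Xcols[, candidates, drop = FALSE]
  cn2 <- colSums(Xc^2)
  resid2 <- cn2 - colSums(crossprod(Q, Xc)^2)
  resid2[resid2 < 0] <- 0
  if (max(resid2) <= tol * max(cn2, 1)) return(NA_integer_)
  candidates[which.max(resid2)]
}

#' Select effective wavelengths by the successive projections algorithm
#'
#' For every starting column, grows a projection chain of maximally
#' independent columns up to `max_vars`; every chain prefix of length
#' `min_vars..max_vars` is scored by the RMSE of a multiple linear
#' regression fitted on a seeded calibration split and evaluated on the
#' held-out validation rows. The (start, length) prefix with minimum
#' validation RMSE wins.
#'
#' @param x `spectrum_set` or samples x bands matrix (calibration rows only).
#' @param y reference values.
#' @param cfg a [spa_config()]; `max_vars` must stay below the number of
#'   calibration rows so the MLR is solvable.
#' @return A `selection_result` with `per_iteration` holding the best RMSE
#'   per chain length and `chosen_iteration` the winning chain length.
#' @export
spa_select <- function(x, y, cfg = spa_config()) {
  wl <- if (inherits(x, "spectrum_set")) x$wavelengths else seq_len(ncol(x))
  X <- if (inherits(x, "spectrum_set")) x$X else as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  max_vars <- min(cfg$max_vars, p)
  if (max_vars >= n) {
    stop("max_vars (", max_vars, ") must be < samples (", n, ") for MLR")
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(cfg$seed)
  n_val <- max(1L, round(cfg$validation_fraction * n))
  val <- sort(sample(n, n_val))
  tr <- setdiff(seq_len(n), val)
  # centred columns for the projection geometry
  Xc <- scale(X, scale = FALSE)

  best <- list(rmse = Inf, chain = NULL, len = NA_integer_)
  len_best <- rep(Inf, max_vars)
  for (start in seq_len(p)) {
    chain <- start
    while (length(chain) < max_vars) {
      nxt <- spa_projection_step(Xc, chain)
      if (is.na(nxt)) break
      chain <- c(chain, nxt)
    }
    for (L in seq(cfg$min_vars, min(max_vars, length(chain)))) {
      sub <- chain[seq_len(L)]
      rm_ <- mlr_val_rmse(X[tr, sub, drop = FALSE], y[tr],
                          X[val, sub, drop = FALSE], y[val])
      if (rm_ < len_best[L]) len_best[L] <- rm_
      if (rm_ < best$rmse) best <- list(rmse = rm_, chain = sub, len = L)
    }
  }
  sel <- sort(best$chain)
  structure(list(selected_indices = sel,
                 selected_wavelengths = wl[sel],
                 per_iteration = data.frame(
                   subset_size = seq_len(max_vars),
                   rmse = ifelse(is.finite(len_best), len_best, NA_real_)),
                 chosen_iteration = best$len, method = "SPA",
                 min_rmse = best$rmse),
            class = "selection_result")
}

# ordinary multiple linear regression with intercept; validation RMSE
mlr_val_rmse <- function(Xtr, ytr, Xval, yval) {
  fit <- stats::lm.fit(cbind(1, Xtr), ytr)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- as.numeric(cbind(1, Xval) %*% beta)
  sqrt(mean((yval - pred)^2))
}

#' Serialize a selection result to JSON
#'
#' Wavelengths are printed at two decimals, matching the conventional
#' reporting style for selected-band tables.
#'
#' @param res a `selection_result`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection_json <- function(res, path) {
  stopifnot(inherits(res, "selection_result"))
  obj <- list(method = res$method,
              n_selected = length(res$selected_indices),
              selected_indices = res$selected_indices,
              selected_wavelengths =
                as.numeric(sprintf("%.2f", res$selected_wavelengths)),
              chosen_iteration = res$chosen_iteration,
              per_iteration = res$per_iteration)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a selection result from JSON
#'
#' @param path JSON written by [write_selection_json()].
#' @return A `selection_result`.
#' @export
read_selection_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected_indices = as.integer(obj$selected_indices),
                 selected_wavelengths = as.numeric(obj$selected_wavelengths),
                 per_iteration = as.data.frame(obj$per_iteration),
                 chosen_iteration = obj$chosen_iteration,
                 method = obj$method),
            class = "selection_result")
}
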