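#' Feature-selection configuration
#'
#' Parameters of the three-step survival-feature selection: the Spearman
#' redundancy threshold, the repeated cross-validated LASSO settings, and
#' the feature-count cap implied by the 10:1 events-per-variable rule
#' (fewer than 11 features for a 114-patient primary cohort).
#'
#' @param spearman_threshold absolute Spearman correlation above which a
#'   feature is redundant (default 0.90).
#' @param folds CV folds (default 4).
#' @param repeats CV repetitions (default 100).
#' @param max_features exclusive cap on selected features (default 11).
#' @param lambda_grid optional descending lambda sequence; defaults to the
#'   data-derived glmnet path.
#' @param seed integer seed for fold assignment.
#' @return a `selection_config` list.
#' @export
selection_config <- function(spearman_threshold = 0.90, folds = 4L,
                             repeats = 100L, max_features = 11L,
                             lambda_grid = NULL, seed = 1L) {
  if (!(spearman_threshold > 0 && spearman_threshold <= 1)) {
    abort("`spearman_threshold` must be in (0, 1]")
  }
  if (folds < 2L) abort("`folds` must be >= 2")
  if (max_features < 1L) abort("`max_features` must be >= 1")
  structure(
    list(spearman_threshold = spearman_threshold, folds = as.integer(folds),
         repeats = as.integer(repeats),
         max_features = as.integer(max_features),
         lambda_grid = lambda_grid, seed = as.integer(seed)),
    class = "selection_config"
  )
}

#' Spearman redundancy filter
#'
#' Greedy scan in the deterministic feature order of the matrix: a feature
#' is dropped when its absolute Spearman correlation with any
#' already-retained feature exceeds the threshold. Constant columns are
#' dropped first (undefined correlation). Invariant to patient ordering.
#'
#' @param features tibble or matrix of patients x features; a `patient_id`
#'   column, if present, is ignored.
#' @param threshold absolute correlation cutoff (default 0.90).
#' @return list with `retained` (character keys), `drop_log` (tibble:
#'   `dropped`, `culprit`, `abs_rho`, `reason`).
#' @export
spearman_filter <- function(features, threshold = 0.90) {
  x <- as.data.frame(features)
  x$patient_id <- NULL
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort("need >= 2 patients")
  if (!all(is.finite(x))) abort("feature matrix must be finite")
  keys <- colnames(x)
  sds <- apply(x, 2, sd)
  const <- sds == 0
  drop_log <- tibble(
    dropped = keys[const], culprit = NA_character_,
    abs_rho = NA_real_, reason = "constant column (undefined correlation)"
  )
  keys <- keys[!const]
  if (!length(keys)) return(list(retained = character(), drop_log = drop_log))
  # standardized column ranks: crossprod gives Spearman rho
  z <- apply(x[, keys, drop = FALSE], 2, rank)
  z <- scale(z)
  n <- nrow(z)
  retained_idx <- integer(0)
  dropped <- character(0); culprit <- character(0); rho_at <- numeric(0)
  block <- 256L
  starts <- seq(1L, length(keys), by = block)
  zret <- NULL
  for (s in starts) {
    e <- min(s + block - 1L, length(keys))
    zb <- z[, s:e, drop = FALSE]
    c_prev <- if (length(retained_idx))
      abs(crossprod(zret, zb)) / (n - 1) else
      matrix(0, 0, e - s + 1L)
    c_in <- abs(crossprod(zb)) / (n - 1)
    kept_in_block <- integer(0)
    for (j in seq_len(e - s + 1L)) {
      rho_prev <- if (nrow(c_prev)) c_prev[, j] else numeric(0)
      rho_blk <- if (length(kept_in_block)) c_in[kept_in_block, j] else numeric(0)
      rho <- c(rho_prev, rho_blk)
      if (length(rho) && max(rho) > threshold) {
        w <- which.max(rho)
        culp <- if (w <= length(rho_prev)) keys[retained_idx[w]]
                else keys[s - 1L + kept_in_block[w - length(rho_prev)]]
        dropped <- c(dropped, keys[s - 1L + j])
        culprit <- c(culprit, culp)
        rho_at <- c(rho_at, max(rho))
      } else {
        kept_in_block <- c(kept_in_block, j)
      }
    }
    if (length(kept_in_block)) {
      retained_idx <- c(retained_idx, s - 1L + kept_in_block)
      zret <- z[, retained_idx, drop = FALSE]
    }
  }
  drop_log <- dplyr::bind_rows(
    drop_log,
    tibble(dropped = dropped, culprit = culprit, abs_rho = rho_at,
           reason = "redundant (|rho| > threshold)")
  )
  list(retained = keys[retained_idx], drop_log = drop_log)
}

# glmnet warns on every small class/fold; expected at small n, muffled
muffle_small_class <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Repeated cross-validated LASSO feature selection
#'
#' L1-penalized logistic regression over a descending lambda path, with the
#' binomial deviance averaged over `repeats` randomized `folds`-fold
#' cross-validations. The selected lambda minimizes the mean CV deviance
#' subject to the non-zero coefficient count staying under `max_features`;
#' when the unconstrained minimum breaks the cap, lambda is increased along
#' the path to the first point that satisfies it. Columns are standardized
#' internally; returned coefficients are on the original feature scale.
#'
#' @param x numeric matrix (patients x features) with column names.
#' @param y binary outcome (0/1 or logical), the 5-year OS label.
#' @param config a [selection_config()].
#' @return a `lasso_selection`: list with `coefficients` (tibble `term`,
#'   `estimate`; intercept term `(Intercept)`), `lambda`, `path` (tibble
#'   `lambda`, `mean_deviance`, `sd_deviance`, `nonzero`), `config`.
#' @export
lasso_select <- function(x, y, config = selection_config()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) abort("degenerate outcome: single class")
  set.seed(child_seed(config$seed, "lasso"))
  fit0 <- muffle_small_class(
    glmnet::glmnet(x, y, family = "binomial", lambda = config$lambda_grid)
  )
  lambda <- fit0$lambda
  n <- nrow(x)
  dev_sum <- matrix(NA_real_, config$repeats, length(lambda))
  for (r in seq_len(config$repeats)) {
    # class-stratified fold assignment keeps both outcomes in every fold
    foldid <- integer(n)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep(seq_len(config$folds),
                                length.out = length(idx)))
    }
    cv <- muffle_small_class(
      glmnet::cv.glmnet(x, y, family = "binomial",
                        type.measure = "deviance", lambda = lambda,
                        foldid = foldid)
    )
    dev_sum[r, seq_along(cv$lambda)] <- cv$cvm[match(lambda, cv$lambda)]
  }
  mean_dev <- colMeans(dev_sum, na.rm = TRUE)
  sd_dev <- apply(dev_sum, 2, sd, na.rm = TRUE)
  nz <- fit0$df
  ok <- is.finite(mean_dev)
  idx_opt <- which(ok)[which.min(mean_dev[ok])]
  idx <- idx_opt
  # lambda decreases with index; move toward larger lambda until under cap
  while (idx >= 1L && nz[idx] >= config$max_features) idx <- idx - 1L
  if (idx < 1L) abort("no lambda on the path satisfies the feature cap")
  beta <- coef(fit0, s = lambda[idx])
  nz_terms <- which(beta[-1] != 0)
  structure(
    list(
      coefficients = tibble(
        term = c("(Intercept)", rownames(beta)[-1][nz_terms]),
        estimate = c(beta[1], beta[-1][nz_terms])
      ),
      lambda = lambda[idx],
      lambda_opt_unconstrained = lambda[idx_opt],
      path = tibble(lambda = lambda, mean_deviance = mean_dev,
                    sd_deviance = sd_dev, nonzero = as.integer(nz)),
      config = config
    ),
    class = "lasso_selection"
  )
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf(
    "<lasso_selection> lambda = %.4g, %d non-zero features\n",
    x$lambda, nrow(x$coefficients) - 1L
  ))
  invisible(x)
}

#' @rdname lasso_select
#' @param x a `lasso_selection`.
#' @param ... unused.
#' @export
tidy.lasso_selection <- function(x, ...) x$coefficients
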