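# Forward stepwise multiple linear regression of log kw on molecular
# descriptors: the model-building step of the isomer-recognition QSRR
# workflow. Ordinary least squares is delegated to stats::lm; the
# stepwise search, its partial-F entry rule and the reporting layer are
# implemented here.

#' Split species into training and validation sets
#'
#' Uniform random split without replacement, reproducible for a fixed
#' seed. The study design this mirrors uses 29 species split 24/5.
#'
#' @param ids Character vector of species labels.
#' @param n_val Number of validation species.
#' @param seed Integer seed (local to this call; the global RNG state is
#'   untouched).
#' @return Object of class `split_plan`: `seed`, `train`, `validation`.
#' @export
split_train_validation <- function(ids, n_val, seed) {
  if (n_val >= length(ids)) {
    stop("n_val (", n_val, ") must be smaller than the number of species (",
         length(ids), ")")
  }
  val <- with_seed(seed, sample(ids, n_val))
  structure(list(seed = seed, train = setdiff(ids, val), validation = val),
            class = "split_plan")
}

#' Fit an ordinary least squares QSRR model
#'
#' Least-squares fit of `y` (log kw) on the given descriptor columns,
#' with the full statistics block: R2, adjusted R2, the overall F
#' statistic `F = (R2/p) / ((1 - R2)/(n - p - 1))`, the standard error of
#' estimate `s = sqrt(RSS / (n - p - 1))` and two-sided t-test p-values
#' per coefficient.
#'
#' @param X Data frame or matrix of descriptor columns (names may be
#'   non-syntactic Dragon identifiers).
#' @param y Numeric response (log kw).
#' @param ids Optional row labels stored as the training ids.
#' @return Object of class `qsrr_model`: `intercept`, named
#'   `coefficients`, `stats` (r2, adj_r2, F, p_model, s, n, p),
#'   `p_values`, `residuals`, `fitted`, `train_ids`, `descriptors`.
#' @export
fit_ols <- function(X, y, ids = NULL) {
  X <- as.data.frame(X, check.names = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n <= p + 1L) stop("need n > p + 1 observations (n = ", n,
                        ", p = ", p, ")")
  const <- vapply(X, function(col) sd(col) == 0, TRUE)
  if (any(const)) {
    stop("constant descriptor column(s): ",
         paste(names(X)[const], collapse = ", "))
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1L):ncol(mm)]]
    stop("singular design matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- lm(y ~ ., data = cbind(y = y, X))
  # summary.lm warns on exactly collinear-free perfect fits (s = 0);
  # those are legitimate here (noiseless simulations)
  sm <- suppressWarnings(summary(fit))
  cf <- coef(fit)
  rss <- sum(fit$residuals^2)
  dfres <- n - p - 1L
  r2 <- sm$r.squared
  Fstat <- if (p > 0) (r2 / p) / ((1 - r2) / dfres) else NA_real_
  structure(list(
    intercept = unname(cf[1]),
    coefficients = if (p > 0) setNames(unname(cf[-1]), names(X))
                   else setNames(numeric(0), character(0)),
    descriptors = names(X),
    stats = list(r2 = r2, adj_r2 = sm$adj.r.squared, F = Fstat,
                 p_model = if (p > 0)
                   pf(Fstat, p, dfres, lower.tail = FALSE) else NA_real_,
                 s = sqrt(rss / dfres), rss = rss, n = n, p = p,
                 df_residual = dfres),
    p_values = setNames(sm$coefficients[, 4],
                        c("(Intercept)", names(X))[seq_len(p + 1L)]),
    std_errors = setNames(sm$coefficients[, 2],
                          c("(Intercept)", names(X))[seq_len(p + 1L)]),
    residuals = unname(fit$residuals),
    fitted = unname(fit$fitted.values),
    train_ids = ids),
    class = "qsrr_model")
}

#' @export
print.qsrr_model <- function(x, ...) {
  cat("<qsrr_model> log kw ~", if (length(x$descriptors))
    paste(x$descriptors, collapse = " + ") else "1", "\n")
  cat(sprintf("  n = %d, R2 = %.3f, F = %.2f, s = %.4f\n",
              x$stats$n, x$stats$r2, x$stats$F, x$stats$s))
  invisible(x)
}

#' Forward stepwise descriptor selection
#'
#' Greedy model building: at each step the candidate whose addition gives
#' the largest partial F statistic enters, provided that statistic
#' exceeds `f_to_enter`; the search stops at `max_terms` terms (a hard
#' cap guarding against over-fitting) or when no candidate qualifies.
#' Ties in partial F are broken lexicographically on the descriptor name,
#' so the selection path is fully deterministic.
#'
#' @param X Data frame of candidate descriptor columns.
#' @param y Numeric response (log kw).
#' @param max_terms Maximum number of descriptors (default 4).
#' @param f_to_enter Partial-F entry threshold (default 4.0).
#' @param ids Optional species labels passed to the final [fit_ols()].
#' @return List with `selected` (ordered descriptor names), `model` (the
#'   final `qsrr_model`), and `path` (per-step partial F of the entering
#'   descriptor).
#' @export
forward_stepwise <- function(X, y, max_terms = 4L, f_to_enter = 4.0,
                             ids = NULL) {
  X <- as.data.frame(X, check.names = FALSE)
  if (ncol(X) < 1L) stop("no candidate descriptors")
  keep <- vapply(X, function(col) sd(col) > 0, TRUE)
  X <- X[, keep, drop = FALSE]
  n <- nrow(X)
  selected <- character(0)
  path <- numeric(0)
  mm_sel <- matrix(1, n, 1)
  rss_cur <- sum((y - mean(y))^2)
  while (length(selected) < max_terms) {
    cands <- setdiff(names(X), selected)
    if (!length(cands)) break
    rss_new <- vapply(cands, function(cn) {
      f <- stats::lm.fit(cbind(mm_sel, X[[cn]]), y)
      if (any(is.na(f$coefficients))) return(NA_real_)  # collinear add
      sum(f$residuals^2)
    }, 0)
    dfres <- n - (length(selected) + 2L)  # after adding one term
    partF <- (rss_cur - rss_new) / (rss_new / dfres)
    partF[is.na(partF)] <- -Inf
    best <- max(partF)
    if (!is.finite(best) || best < f_to_enter) break
    # lexicographic tie-break for full determinism
    winner <- sort(cands[partF >= best - 1e-12])[1]
    selected <- c(selected, winner)
    path <- c(path, setNames(partF[match(winner, cands)], winner))
    mm_sel <- cbind(mm_sel, X[[winner]])
    rss_cur <- rss_new[match(winner, cands)]
  }
  model <- if (length(selected)) {
    fit_ols(X[, selected, drop = FALSE], y, ids = ids)
  } else {
    # intercept-only model
    structure(list(
      intercept = mean(y), coefficients = setNames(numeric(0), character(0)),
      descriptors = character(0),
      stats = list(r2 = 0, adj_r2 = 0, F = NA_real_, p_model = NA_real_,
                   s = sd(y), rss = sum((y - mean(y))^2), n = n, p = 0L,
                   df_residual = n - 1L),
      p_values = c(`(Intercept)` = NA_real_),
      std_errors = c(`(Intercept)` = sd(y) / sqrt(n)),
      residuals = y - mean(y), fitted = rep(mean(y), n),
      train_ids = ids), class = "qsrr_model")
  }
  list(selected = selected, model = model, path = path)
}

#' Predict log kw for new species
#'
#' @param model A `qsrr_model`.
#' @param X_new Data frame containing at least the model's descriptor
#'   columns.
#' @return Numeric vector of predicted log kw values.
#' @export
predict_logkw <- function(model, X_new) {
  X_new <- as.data.frame(X_new, check.names = FALSE)
  missing <- setdiff(model$descriptors, names(X_new))
  if (length(missing)) {
    stop("descriptor column(s) missing from new data: ",
         paste(missing, collapse = ", "))
  }
  if (!length(model$descriptors)) {
    return(rep(model$intercept, nrow(X_new)))
  }
  model$intercept +
    as.vector(as.matrix(X_new[, model$descriptors, drop = FALSE]) %*%
              model$coefficients)
}

#' External validation of a QSRR model
#'
#' Predicts log kw for a held-out validation set and reports the root
#' mean squared error of prediction (RMSEP), the external R2 (1 -
#' PRESS / total sum of squares of the validation responses about the
#' training mean), and per-species residuals.
#'
#' @param model A `qsrr_model`.
#' @param X_val Validation descriptors.
#' @param y_val Validation log kw values.
#' @param ids Optional validation species labels.
#' @return Object of class `qsrr_validation`: `rmsep`, `r2_pred`,
#'   `residuals` (data frame id/observed/predicted/residual), `n_val`.
#' @export
validate_external <- function(model, X_val, y_val, ids = NULL) {
  if (!is.null(ids) && !is.null(model$train_ids) &&
      length(intersect(ids, model$train_ids))) {
    stop("validation ids overlap the training set: ",
         paste(intersect(ids, model$train_ids), collapse = ", "))
  }
  pred <- predict_logkw(model, X_val)
  res <- y_val - pred
  ybar <- if (!is.null(model$fitted)) {
    mean(model$fitted + model$residuals)
  } else {
    mean(y_val)
  }
  structure(list(
    rmsep = sqrt(mean(res^2)),
    r2_pred = 1 - sum(res^2) / sum((y_val - ybar)^2),
    residuals = data.frame(
      id = if (is.null(ids)) seq_along(y_val) else ids,
      observed = y_val, predicted = pred, residual = res,
      stringsAsFactors = FALSE),
    n_val = length(y_val)), class = "qsrr_validation")
}

#' @export
print.qsrr_validation <- function(x, ...) {
  cat(sprintf("<qsrr_validation> n = %d, RMSEP = %.4f, R2_pred = %.3f\n",
              x$n_val, x$rmsep, x$r2_pred))
  invisible(x)
}

#' Serialize / restore a QSRR model as JSON
#'
#' @param model A `qsrr_model`.
#' @param path JSON path.
#' @param split Optional `split_plan` stored alongside.
#' @return `path` (write); a `qsrr_model` (read).
#' @export
write_qsrr_model <- function(model, path, split = NULL) {
  doc <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              descriptors = model$descriptors,
              stats = model$stats,
              p_values = as.list(model$p_values),
              train_ids = model$train_ids)
  if (!is.null(split)) {
    doc$split <- list(seed = split$seed, train = split$train,
                      validation = split$validation)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_qsrr_model
#' @export
read_qsrr_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    intercept = doc$intercept,
    coefficients = setNames(unlist(doc$coefficients),
                            names(doc$coefficients)),
    descriptors = doc$descriptors,
    stats = doc$stats,
    p_values = setNames(unlist(doc$p_values), names(doc$p_values)),
    train_ids = doc$train_ids), class = "qsrr_model")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded generators stay
#' local to each call; every stochastic routine in the package takes an
#' explicit seed and routes through this helper.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
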