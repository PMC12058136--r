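#' Nodewise MGM configuration
#'
#' Controls the nodewise estimation of the binary (Ising-type) graphical
#' model: edge aggregation rule, penalty selection, grid size, and the single
#' seed that governs all randomness (fold splits).
#'
#' @param rule Edge rule: `"AND"` (edge iff both directed coefficients are
#'   nonzero; default, conservative) or `"OR"` (either nonzero).
#' @param lambda_selection `"cv"` (cross-validated held-out binomial deviance,
#'   default) or `"ebic"` (extended BIC).
#' @param cv_folds Number of CV folds (>= 2, default 10).
#' @param lambda_grid_size Number of penalties on the log-spaced grid
#'   (default 30).
#' @param ebic_gamma EBIC gamma (>= 0, default 0.25).
#' @param debias If `TRUE`, refit an unpenalized logistic regression on each
#'   node's selected support before aggregation, removing lasso shrinkage from
#'   the reported edge weights (default `FALSE`).
#' @param seed Integer seed for fold assignment.
#' @return A list of class `mgm_config`.
#' @export
mgm_config <- function(rule = c("AND", "OR"),
                       lambda_selection = c("cv", "ebic"),
                       cv_folds = 10, lambda_grid_size = 30,
                       ebic_gamma = 0.25, debias = FALSE, seed = 1) {
  rule <- match.arg(rule)
  lambda_selection <- match.arg(lambda_selection)
  stopifnot(cv_folds >= 2, lambda_grid_size >= 2, ebic_gamma >= 0)
  structure(list(rule = rule, lambda_selection = lambda_selection,
                 cv_folds = as.integer(cv_folds),
                 lambda_grid_size = as.integer(lambda_grid_size),
                 ebic_gamma = ebic_gamma, debias = isTRUE(debias),
                 seed = as.integer(seed)),
            class = "mgm_config")
}

#' Penalty grid for one nodewise regression
#'
#' Log-spaced, strictly decreasing grid from `lambda_max` (the smallest
#' penalty at which all coefficients are zero, by the KKT conditions:
#' `max_j |<x_j, y - mean(y)>| / n`) down to `1e-3 * lambda_max`.
#'
#' @param y Binary response vector.
#' @param X Design matrix.
#' @param grid_size Number of grid points (>= 2).
#' @return Decreasing numeric vector of length `grid_size`.
#' @export
lambda_path <- function(y, X, grid_size = 30) {
  stopifnot(grid_size >= 2)
  n <- length(y)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (lam_max <= 0) lam_max <- 1e-4  # degenerate: uncorrelated/constant data
  exp(seq(log(lam_max), log(1e-3 * lam_max), length.out = grid_size))
}

# glmnet requires >= 2 predictor columns; pad with an all-zero column that
# can never enter the active set
pad_design <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `..pad..` = 0)
}

#' L1-penalized logistic regression at a single penalty
#'
#' Minimizes `-(1/n) loglik + lambda * sum(|beta_j|)` with an unpenalized
#' intercept, via glmnet coordinate descent with `standardize = FALSE` (so on
#' 0/1 designs the coefficients estimate Ising couplings directly). A
#' constant response yields a flagged intercept-only fit rather than an
#' error.
#'
#' @inheritParams lambda_path
#' @param lambda Penalty (>= 0).
#' @return List with `intercept`, named `beta`, `lambda` and `degenerate`.
#' @export
l1_logistic <- function(y, X, lambda) {
  stopifnot(lambda >= 0, all(y %in% c(0, 1)))
  vars <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  if (length(unique(y)) < 2) {
    warning("constant response: returning degenerate intercept-only fit")
    pbar <- min(max(mean(y), 1e-12), 1 - 1e-12)
    return(list(intercept = stats::qlogis(pbar),
                beta = stats::setNames(rep(0, ncol(X)), vars),
                lambda = lambda, degenerate = TRUE))
  }
  n <- length(y)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / n
  if (lambda >= lam_max && lambda > 0) {
    # full shrinkage: KKT gives the null model exactly
    return(list(intercept = stats::qlogis(mean(y)),
                beta = stats::setNames(rep(0, ncol(X)), vars),
                lambda = lambda, degenerate = FALSE))
  }
  # glmnet warm-starts down a path; include the target value in the sequence
  lseq <- sort(unique(c(lambda_path(y, X, 15), lambda)), decreasing = TRUE)
  lseq <- lseq[lseq >= lambda]
  Xp <- pad_design(X)
  fit <- glmnet::glmnet(Xp, y, family = "binomial", lambda = lseq,
                        standardize = FALSE, thresh = 1e-10)
  k <- which.min(abs(fit$lambda - lambda))
  list(intercept = as.numeric(fit$a0[k]),
       beta = stats::setNames(as.numeric(fit$beta[seq_len(ncol(X)), k]), vars),
       lambda = lambda, degenerate = FALSE)
}

#' Cross-validated penalty selection
#'
#' Deterministic fold assignment given `seed`; the selected penalty minimizes
#' the mean held-out binomial deviance over the grid, with ties broken toward
#' the larger (sparser) penalty. Folds whose training response is constant
#' are dropped with a warning.
#'
#' @inheritParams lambda_path
#' @param folds Number of folds (>= 2; `n >= folds` required).
#' @param grid Penalty grid; defaults to [lambda_path()].
#' @param seed Integer seed for the fold split.
#' @return List with `lambda` (the selected penalty), `cvm` (mean held-out
#'   deviance per grid value), `grid` and `foldid`.
#' @export
select_lambda_cv <- function(y, X, folds = 10, grid = NULL, seed = 1) {
  n <- length(y)
  stopifnot(folds >= 2, n >= folds)
  if (is.null(grid)) grid <- lambda_path(y, X, 30)
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  dev_sum <- rep(0, length(grid))
  n_used <- 0L
  for (k in seq_len(folds)) {
    tr <- foldid != k
    if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) {
      warning(sprintf("fold %d dropped: constant response", k))
      next
    }
    Xp <- pad_design(X)
    fit <- glmnet::glmnet(Xp[tr, , drop = FALSE], y[tr], family = "binomial",
                          lambda = grid, standardize = FALSE, thresh = 1e-10)
    ph <- stats::predict(fit, Xp[!tr, , drop = FALSE], s = grid,
                         type = "response", exact = FALSE)
    ph <- pmin(pmax(ph, 1e-12), 1 - 1e-12)
    yk <- y[!tr]
    dev_k <- -2 * colSums(yk * log(ph) + (1 - yk) * log(1 - ph))
    if (ncol(ph) == length(grid)) {
      dev_sum <- dev_sum + dev_k
      n_used <- n_used + sum(!tr)
    }
  }
  if (n_used == 0L) stop("all folds degenerate; cannot cross-validate", call. = FALSE)
  cvm <- dev_sum / n_used
  best <- min(cvm)
  # ties (to numerical tolerance) resolved toward the larger, sparser penalty
  lambda <- max(grid[cvm <= best + 1e-10])
  list(lambda = lambda, cvm = cvm, grid = grid, foldid = foldid)
}

# EBIC over the lasso path, evaluated on unpenalized ML refits of each
# distinct support (shrunken deviances distort the size/fit trade-off).
# grid[1] = lambda_max has the empty support by definition of the grid.
ebic_select <- function(y, X, grid, gamma) {
  n <- length(y)
  p <- ncol(X)
  fit <- glmnet::glmnet(pad_design(X), y, family = "binomial", lambda = grid,
                        standardize = FALSE, thresh = 1e-10)
  B <- as.matrix(fit$beta)[seq_len(ncol(X)), , drop = FALSE]
  B[, 1] <- 0
  supports <- apply(B != 0, 2, function(z)
    paste0("s", paste(which(z), collapse = ",")))
  ebic <- rep(NA_real_, length(grid))
  cache <- new.env(parent = emptyenv())
  for (k in seq_along(grid)) {
    sp <- supports[k]
    if (is.null(cache[[sp]])) {
      idx <- if (sp == "s") integer(0) else
        as.integer(strsplit(sub("^s", "", sp), ",")[[1]])
      dev <- if (length(idx) == 0) {
        -2 * sum(stats::dbinom(y, 1, mean(y), log = TRUE))
      } else {
        suppressWarnings(stats::glm.fit(
          cbind(1, X[, idx, drop = FALSE]), y,
          family = stats::binomial()))$deviance
      }
      cache[[sp]] <- dev + length(idx) * log(n) +
        2 * gamma * length(idx) * log(p)
    }
    ebic[k] <- cache[[sp]]
  }
  max(grid[ebic <= min(ebic) + 1e-10])
}

#' Estimate the disease network by nodewise penalized logistic regression
#'
#' Fits one L1-penalized logistic regression per disease on all other
#' diseases (penalty chosen per node by CV deviance or EBIC), then aggregates
#' the directed coefficient matrix into an undirected [pairwise_network()]:
#' under the AND rule an edge (s, t) is present iff both `beta[s, t]` and
#' `beta[t, s]` are nonzero, with weight their mean; under the OR rule it is
#' present if either is nonzero, the absent coefficient entering the mean as
#' 0. When the two coefficients disagree in sign the edge is kept with
#' `sign_consistent = FALSE` and weight equal to the mean magnitude.
#' Aggregated weights below 1e-6 in absolute value are dropped as numerical
#' noise. Constant disease columns are retained as flagged isolated nodes.
#'
#' @param cohort A validated cohort tibble (see [validate_cohort()]).
#' @param config An [mgm_config()].
#' @return An object of class `mgm_fit` with elements:
#'   `nodes` (tibble: disease, intercept, lambda, df, accuracy, degenerate),
#'   `B` (p x p directed coefficient matrix, `B[s, t]` = coefficient of t in
#'   the regression of s), `network` (the aggregated [pairwise_network()]),
#'   and `config`.
#' @export
fit_nodewise <- function(cohort, config = mgm_config()) {
  stopifnot(inherits(config, "mgm_config"))
  catalog <- cohort_catalog(cohort)
  X <- disease_matrix(cohort, catalog)
  storage.mode(X) <- "double"
  p <- ncol(X)
  n <- nrow(X)
  if (p < 2) stop("need at least 2 diseases", call. = FALSE)
  if (n < 50) warning("fewer than 50 persons: estimates will be unstable")
  codes <- catalog$code
  B <- matrix(0, p, p, dimnames = list(codes, codes))
  info <- vector("list", p)
  for (s in seq_len(p)) {
    y <- X[, s]
    Xs <- X[, -s, drop = FALSE]
    if (length(unique(y)) < 2) {
      warning(sprintf("disease %s is constant: node kept but isolated", codes[s]))
      pbar <- min(max(mean(y), 1e-12), 1 - 1e-12)
      info[[s]] <- tibble::tibble(
        disease = codes[s], intercept = stats::qlogis(pbar),
        lambda = NA_real_, df = 0L,
        accuracy = mean((pbar > 0.5) == y), degenerate = TRUE)
      next
    }
    grid <- lambda_path(y, Xs, config$lambda_grid_size)
    lam <- if (config$lambda_selection == "cv") {
      select_lambda_cv(y, Xs, folds = config$cv_folds, grid = grid,
                       seed = config$seed + s)$lambda
    } else {
      ebic_select(y, Xs, grid, config$ebic_gamma)
    }
    fit <- l1_logistic(y, Xs, lam)
    beta <- fit$beta
    intercept <- fit$intercept
    if (config$debias && any(beta != 0)) {
      supp <- names(beta)[beta != 0]
      df_glm <- data.frame(y = y, Xs[, supp, drop = FALSE], check.names = FALSE)
      refit <- suppressWarnings(stats::glm(
        y ~ ., data = df_glm, family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
      cf <- stats::coef(refit)
      if (!anyNA(cf) && max(abs(cf[-1])) < 15) {
        intercept <- cf[[1]]
        beta[supp] <- cf[supp]
      }  # near-separated refits fall back to the penalized estimate
    }
    B[s, codes[-s]] <- beta[codes[-s]]
    phat <- stats::plogis(intercept + Xs %*% beta)
    info[[s]] <- tibble::tibble(
      disease = codes[s], intercept = intercept, lambda = lam,
      df = sum(beta != 0), accuracy = mean((phat > 0.5) == y),
      degenerate = FALSE)
  }
  nodes <- dplyr::bind_rows(info)
  net <- aggregate_edges(B, rule = config$rule)
  structure(list(nodes = nodes, B = B, network = net, config = config,
                 n = n, catalog = catalog),
            class = "mgm_fit")
}

aggregate_edges <- function(B, rule = c("AND", "OR"), floor = 1e-6) {
  rule <- match.arg(rule)
  codes <- rownames(B)
  p <- nrow(B)
  rows <- list()
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      bst <- B[s, t]
      bts <- B[t, s]
      present <- if (rule == "AND") bst != 0 && bts != 0 else bst != 0 || bts != 0
      if (!present) next
      consistent <- sign(bst) == sign(bts) || bst == 0 || bts == 0
      w <- if (consistent) mean(c(bst, bts)) else mean(abs(c(bst, bts)))
      if (abs(w) < floor) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        from = codes[s], to = codes[t], weight = w,
        sign_consistent = consistent)
    }
  }
  pairwise_network(codes, dplyr::bind_rows(rows))
}

#' @export
print.mgm_fit <- function(x, ...) {
  cat(sprintf("<mgm_fit: %d diseases, n = %d, rule = %s, %d edges>\n",
              nrow(x$nodes), x$n, x$config$rule, nrow(x$network$edges)))
  invisible(x)
}

#' @export
#' @method tidy mgm_fit
tidy.mgm_fit <- function(x, ...) x$network$edges

#' @export
#' @method glance mgm_fit
glance.mgm_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = nrow(x$nodes), rule = x$config$rule,
    lambda_selection = x$config$lambda_selection,
    n_edges = nrow(x$network$edges),
    mean_accuracy = mean(x$nodes$accuracy),
    min_accuracy = min(x$nodes$accuracy),
    max_accuracy = max(x$nodes$accuracy)
  )
}

#' Write the nodewise fit report as CSV
#'
#' One row per disease: intercept, selected penalty, support size, accuracy
#' and the degenerate flag. The header line records the seed governing all
#' randomness of the fit.
#'
#' @param fit An `mgm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %d", fit$config$seed), con)
  utils::write.csv(as.data.frame(fit$nodes), con, row.names = FALSE)
  invisible(path)
}

#' Per-disease classification accuracy of a nodewise fit
#'
#' For each disease, the proportion of persons whose indicator is correctly
#' predicted by thresholding the fitted conditional probability at 0.5.
#' `"within_sample"` scores the fit on the data it was trained on (for an
#' intercept-only node this is the majority-class rate); `"cv"` refits each
#' node at its selected penalty on the CV training folds (reusing the
#' deterministic fold split) and scores held-out persons.
#'
#' @param fit An `mgm_fit`.
#' @param cohort The cohort the fit was produced from.
#' @param scheme `"within_sample"` or `"cv"`.
#' @return A tibble `disease`, `accuracy`, `scheme`.
#' @export
node_accuracy <- function(fit, cohort, scheme = c("within_sample", "cv")) {
  scheme <- match.arg(scheme)
  catalog <- cohort_catalog(cohort)
  stopifnot(identical(catalog$code, fit$catalog$code))
  X <- disease_matrix(cohort, catalog)
  storage.mode(X) <- "double"
  if (scheme == "within_sample") {
    acc <- vapply(seq_len(ncol(X)), function(s) {
      eta <- fit$nodes$intercept[s] + X[, -s, drop = FALSE] %*% fit$B[s, -s]
      mean((stats::plogis(eta) > 0.5) == X[, s])
    }, numeric(1))
    return(tibble::tibble(disease = catalog$code, accuracy = acc,
                          scheme = scheme))
  }
  folds <- fit$config$cv_folds
  acc <- vapply(seq_len(ncol(X)), function(s) {
    y <- X[, s]
    if (fit$nodes$degenerate[s] || length(unique(y)) < 2) {
      return(mean((mean(y) > 0.5) == y))
    }
    Xs <- X[, -s, drop = FALSE]
    set.seed(fit$config$seed + s)
    foldid <- sample(rep(seq_len(folds), length.out = length(y)))
    ok <- 0
    tot <- 0
    for (k in seq_len(folds)) {
      tr <- foldid != k
      if (length(unique(y[tr])) < 2) next
      f <- l1_logistic(y[tr], Xs[tr, , drop = FALSE], fit$nodes$lambda[s])
      ph <- stats::plogis(f$intercept + Xs[!tr, , drop = FALSE] %*% f$beta)
      ok <- ok + sum((ph > 0.5) == y[!tr])
      tot <- tot + sum(!tr)
    }
    ok / tot
  }, numeric(1))
  tibble::tibble(disease = catalog$code, accuracy = acc, scheme = scheme)
}
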