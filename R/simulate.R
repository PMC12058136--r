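#' Planted block-and-bridge design for a synthetic disease network
#'
#' Describes the ground-truth dependence structure a synthetic cohort is drawn
#' from: disjoint blocks of mutually coupled diseases (the planted
#' multimorbidity patterns), bridge nodes coupled into two or more blocks,
#' isolated nodes with no couplings, and target marginal prevalences.
#'
#' @param blocks Named list of character vectors of disease codes; blocks must
#'   be disjoint.
#' @param bridges List of `list(node =, blocks =, w =)` entries: a bridge node
#'   code, the names (or indices) of the blocks it attaches to, and its
#'   coupling strength to every member of those blocks.
#' @param isolates Character vector of codes with no couplings at all.
#' @param w_in Within-block coupling strength (> 0), shared by all block
#'   pairs.
#' @param prevalence Named numeric vector of target marginal prevalences in
#'   (0, 1), one per code.
#' @param catalog The [disease_catalog()] the design spans; blocks, bridges
#'   and isolates must exactly partition its codes.
#' @return An object of class `planted_design`.
#' @export
planted_design <- function(blocks, bridges = list(), isolates = character(),
                           w_in = 1.0, prevalence,
                           catalog = default_catalog()) {
  stopifnot(is.list(blocks), w_in > 0)
  if (length(blocks) > 0 && is.null(names(blocks))) {
    names(blocks) <- paste0("B", seq_along(blocks))
  }
  bridge_nodes <- vapply(bridges, `[[`, "", "node")
  all_members <- c(unlist(blocks, use.names = FALSE), bridge_nodes, isolates)
  if (anyDuplicated(all_members)) {
    stop("blocks, bridges and isolates must be disjoint", call. = FALSE)
  }
  if (!setequal(all_members, catalog$code)) {
    stop("blocks + bridges + isolates must partition the catalog", call. = FALSE)
  }
  for (b in bridges) {
    bl <- b$blocks
    if (is.numeric(bl)) bl <- names(blocks)[bl]
    if (!all(bl %in% names(blocks))) stop("unknown block in bridge spec", call. = FALSE)
    if (is.null(b$w) || b$w == 0) stop("bridge coupling w must be nonzero", call. = FALSE)
  }
  stopifnot(is.numeric(prevalence), !is.null(names(prevalence)))
  if (!setequal(names(prevalence), catalog$code) ||
      any(prevalence <= 0) || any(prevalence >= 1)) {
    stop("prevalence must name every code, with values in (0, 1)", call. = FALSE)
  }
  structure(list(blocks = blocks, bridges = bridges, isolates = isolates,
                 w_in = w_in, prevalence = prevalence[catalog$code],
                 catalog = catalog),
            class = "planted_design")
}

#' Default 32-disease planted design
#'
#' Mirrors, at desk scale, the qualitative structure reported for survey
#' multimorbidity networks: five disease blocks (sizes 6, 6, 5, 5, 4) standing
#' for cardiovascular, musculoskeletal, mental, respiratory and
#' digestive/other patterns; two bridge nodes (hypertension D1 joining the
#' cardiovascular and musculoskeletal blocks, hepatic dysfunction D19 joining
#' the respiratory and digestive blocks); four isolated conditions; and
#' marginal prevalences spread over roughly 3--40%.
#'
#' @param w_in Within-block coupling (default 1.0).
#' @param w_bridge Bridge coupling (default 0.8).
#' @return A [planted_design()].
#' @export
default_design <- function(w_in = 1.0, w_bridge = 0.8) {
  blocks <- list(
    cardiovascular  = c("D2", "D3", "D4", "D12", "D15", "D23"),
    musculoskeletal = c("D6", "D7", "D8", "D14", "D27", "D32"),
    mental          = c("D20", "D21", "D22", "D24", "D28"),
    respiratory     = c("D9", "D10", "D11", "D16", "D18"),
    digestive       = c("D13", "D26", "D29", "D30")
  )
  bridges <- list(
    list(node = "D1", blocks = c("cardiovascular", "musculoskeletal"), w = w_bridge),
    list(node = "D19", blocks = c("respiratory", "digestive"), w = w_bridge)
  )
  isolates <- c("D5", "D17", "D25", "D31")
  prevalence <- c(
    D1 = 0.40, D2 = 0.06, D3 = 0.07, D4 = 0.10, D5 = 0.15, D6 = 0.25,
    D7 = 0.22, D8 = 0.28, D9 = 0.15, D10 = 0.08, D11 = 0.09, D12 = 0.18,
    D13 = 0.06, D14 = 0.10, D15 = 0.30, D16 = 0.12, D17 = 0.10, D18 = 0.09,
    D19 = 0.04, D20 = 0.14, D21 = 0.16, D22 = 0.05, D23 = 0.04, D24 = 0.12,
    D25 = 0.10, D26 = 0.08, D27 = 0.12, D28 = 0.10, D29 = 0.05, D30 = 0.18,
    D31 = 0.07, D32 = 0.20
  )
  planted_design(blocks, bridges, isolates, w_in = w_in, prevalence = prevalence)
}

#' True edge set of a planted design
#'
#' @param design A [planted_design()].
#' @return A tibble `from`, `to`, `weight` of all planted couplings,
#'   canonically ordered.
#' @export
design_edges <- function(design) {
  params <- build_planted_ising(design, calibrate = "mean_field")
  W <- params$W
  codes <- rownames(W)
  idx <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  tibble::tibble(from = codes[idx[, 1]], to = codes[idx[, 2]],
                 weight = W[idx])
}

.calibration_cache <- new.env(parent = emptyenv())

#' Build Ising parameters from a planted design
#'
#' Assembles the symmetric coupling matrix `W` (zero diagonal; `w_in` on every
#' within-block pair, the bridge coupling on every bridge-to-block-member
#' pair, zero elsewhere) and calibrates the threshold vector `h` toward the
#' design's target marginal prevalences. Calibration starts from the
#' mean-field solution — for each node `s`, `h_s` solves
#' `plogis(h_s + sum_t W_st * p_t) = p_s` by 1-D root finding with `p` the
#' target vector — and, by default, is then refined by a short Monte-Carlo
#' loop (`h <- h + logit(target) - logit(simulated marginal)`), because the
#' mean-field approximation substantially overshoots marginals once nodes sit
#' in strongly coupled blocks. Exact marginal matching in an Ising model is
#' intractable in general; the refinement brings marginals within
#' Monte-Carlo error of the targets and is itself verified by simulation in
#' the test-suite. The refinement uses a fixed internal RNG stream (the
#' caller's RNG state is untouched) and its result is cached per design, so
#' repeated builds are cheap and deterministic.
#'
#' @param design A [planted_design()].
#' @param calibrate `"mc"` (mean-field then Monte-Carlo refinement, default)
#'   or `"mean_field"` (root finding only).
#' @param mc_n,mc_sweeps,mc_iter Monte-Carlo refinement controls: chains per
#'   iteration, Gibbs sweeps per iteration, refinement iterations.
#' @return A list with symmetric matrix `W` (dimnames = codes) and named
#'   vector `h`, class `ising_parameters`.
#' @export
build_planted_ising <- function(design, calibrate = c("mc", "mean_field"),
                                mc_n = 3000, mc_sweeps = 100, mc_iter = 30) {
  stopifnot(inherits(design, "planted_design"))
  calibrate <- match.arg(calibrate)
  key <- rlang::hash(list(design, calibrate, mc_n, mc_sweeps, mc_iter))
  if (!is.null(.calibration_cache[[key]])) return(.calibration_cache[[key]])
  codes <- design$catalog$code
  p <- length(codes)
  W <- matrix(0, p, p, dimnames = list(codes, codes))
  for (b in design$blocks) {
    i <- match(b, codes)
    W[i, i] <- design$w_in
  }
  for (br in design$bridges) {
    bl <- br$blocks
    if (is.numeric(bl)) bl <- names(design$blocks)[bl]
    members <- match(unlist(design$blocks[bl], use.names = FALSE), codes)
    i <- match(br$node, codes)
    W[i, members] <- br$w
    W[members, i] <- br$w
  }
  diag(W) <- 0
  targets <- design$prevalence
  h <- vapply(seq_len(p), function(s) {
    field <- sum(W[s, ] * targets)
    stats::uniroot(function(hh) stats::plogis(hh + field) - targets[s],
                   interval = c(-40, 40), tol = 1e-12)$root
  }, numeric(1))
  names(h) <- codes
  if (calibrate == "mc" && any(W != 0)) {
    old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
      else if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(202600L)
    # Robbins-Monro: damped decreasing steps; a full-step update oscillates
    # in strongly coupled blocks
    for (it in seq_len(mc_iter)) {
      nn <- if (it <= mc_iter / 3) mc_n else 2L * mc_n
      X <- sample_ising(structure(list(W = W, h = h),
                                  class = "ising_parameters"),
                        n = nn, burn_in = mc_sweeps)
      ph <- pmin(pmax(colMeans(X), 1 / (2 * nn)), 1 - 1 / (2 * nn))
      h <- h + (0.6 / sqrt(it)) * (stats::qlogis(targets) - stats::qlogis(ph))
    }
  }
  out <- structure(list(W = W, h = h), class = "ising_parameters")
  .calibration_cache[[key]] <- out
  out
}

#' Gibbs-sample binary disease vectors from a pairwise Markov random field
#'
#' Samples `x in {0,1}^p` from `p(x) propto exp(h'x + x'Wx / 2)` using the
#' full conditionals `P(x_s = 1 | rest) = plogis(h_s + sum_t W_st x_t)`. The
#' 0/1 coding means the nodewise logistic coefficients of the model equal the
#' couplings `W` directly, which is what makes parameter recovery by nodewise
#' logistic lasso a clean check. By default each person is an independent
#' chain (fresh random start from the independent `plogis(h)` marginals,
#' `burn_in` full sweeps), matching the independent-respondents assumption of
#' a survey; a single thinned chain is available via `chains = "single"`.
#'
#' @param params An `ising_parameters` list (`W` symmetric, zero diagonal;
#'   `h`).
#' @param n Number of rows (persons) to sample.
#' @param burn_in Burn-in sweeps (default 200).
#' @param thin Thinning interval, only used for `chains = "single"`.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param chains `"independent"` (default) or `"single"`.
#' @return An `n x p` integer 0/1 matrix with disease-code column names.
#' @export
sample_ising <- function(params, n, burn_in = 200, thin = 1, seed = NULL,
                         chains = c("independent", "single")) {
  chains <- match.arg(chains)
  W <- params$W
  h <- params$h
  if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12)) || any(diag(W) != 0)) {
    stop("W must be symmetric with zero diagonal", call. = FALSE)
  }
  stopifnot(n > 0, burn_in >= 0, thin >= 1)
  p <- length(h)
  if (!is.null(seed)) set.seed(seed)
  codes <- names(h) %||% colnames(W) %||% paste0("D", seq_len(p))
  if (chains == "independent") {
    # one chain per row, updated in lock-step: node s is resampled across all
    # rows at once (rows never interact, so this is exact)
    X <- matrix(stats::rbinom(n * p, 1L, rep(stats::plogis(h), each = n)), n, p)
    storage.mode(X) <- "double"
    for (sweep in seq_len(burn_in)) {
      for (s in seq_len(p)) {
        eta <- h[s] + X %*% W[, s]
        X[, s] <- as.numeric(stats::runif(n) < stats::plogis(eta))
      }
    }
  } else {
    x <- as.numeric(stats::rbinom(p, 1L, stats::plogis(h)))
    X <- matrix(0, n, p)
    total <- burn_in + n * thin
    row <- 0L
    for (sweep in seq_len(total)) {
      for (s in seq_len(p)) {
        eta <- h[s] + sum(W[, s] * x)
        x[s] <- as.numeric(stats::runif(1) < stats::plogis(eta))
      }
      if (sweep > burn_in && (sweep - burn_in) %% thin == 0) {
        row <- row + 1L
        X[row, ] <- x
      }
    }
  }
  storage.mode(X) <- "integer"
  colnames(X) <- codes
  X
}

#' Demographic generating spec
#'
#' Category probabilities for the four demographic fields, plus an optional
#' linear predictor (`outcome_link`) used by [generate_regression_cohort()].
#' The defaults reflect a population survey of adults aged 50+: a slight
#' female majority, age bands thinning with age, uniform income quartiles and
#' an education mix dominated by primary schooling.
#'
#' @param gender,age_group,income_q,education Named probability vectors over
#'   the respective category levels (each must sum to 1).
#' @param outcome_link Optional `list(intercept =, beta =)` with `beta` a
#'   named coefficient vector over predictor columns.
#' @return A list of class `demographic_spec`.
#' @export
demographic_spec <- function(
    gender = c(M = 0.48, F = 0.52),
    age_group = c(`50-64` = 0.45, `65-74` = 0.35, `75plus` = 0.20),
    income_q = c(Q1 = 0.25, Q2 = 0.25, Q3 = 0.25, Q4 = 0.25),
    education = c(Primary = 0.45, Secondary = 0.35, Tertiary = 0.20),
    outcome_link = NULL) {
  probs <- list(gender = gender, age_group = age_group,
                income_q = income_q, education = education)
  for (v in names(probs)) {
    pr <- probs[[v]]
    if (!setequal(names(pr), DEMOGRAPHIC_LEVELS[[v]]) ||
        abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
      stop("invalid probability vector for ", v, call. = FALSE)
    }
    probs[[v]] <- pr[DEMOGRAPHIC_LEVELS[[v]]]
  }
  structure(c(probs, list(outcome_link = outcome_link)),
            class = "demographic_spec")
}

#' Attach demographics to a disease matrix
#'
#' Draws the four demographic fields independently of the disease indicators
#' (and of each other) and assembles a validated cohort tibble.
#'
#' @param X An `n x p` 0/1 matrix with disease-code column names.
#' @param spec A [demographic_spec()].
#' @param seed Integer seed; same seed reproduces the cohort exactly.
#' @param catalog Catalog matching the columns of `X`.
#' @return A validated cohort tibble.
#' @export
attach_demographics <- function(X, spec = demographic_spec(), seed = NULL,
                                catalog = default_catalog()) {
  stopifnot(inherits(spec, "demographic_spec"))
  n <- nrow(X)
  if (!is.null(seed)) set.seed(seed)
  draw <- function(v) {
    sample(DEMOGRAPHIC_LEVELS[[v]], n, replace = TRUE, prob = spec[[v]])
  }
  out <- tibble::tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    gender = draw("gender"),
    age_group = draw("age_group"),
    income_q = draw("income_q"),
    education = draw("education")
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  validate_cohort(out, catalog)
}

#' Simulate a full synthetic cohort from a planted design
#'
#' Convenience wrapper: builds the Ising parameters, Gibbs-samples the disease
#' matrix and attaches demographics. Disease and demographic draws use
#' deterministic sub-seeds of `seed`.
#'
#' @param design A [planted_design()].
#' @param n Cohort size.
#' @param spec A [demographic_spec()].
#' @param seed Integer seed.
#' @param burn_in Gibbs burn-in sweeps.
#' @return A validated cohort tibble.
#' @export
simulate_cohort <- function(design = default_design(), n = 2000,
                            spec = demographic_spec(), seed = 1,
                            burn_in = 200) {
  params <- build_planted_ising(design)
  X <- sample_ising(params, n = n, burn_in = burn_in, seed = seed)
  attach_demographics(X, spec, seed = seed + 1L, catalog = design$catalog)
}

#' Generate a cohort with a planted logistic outcome
#'
#' Draws independent binary predictors with given prevalences, demographics
#' from `spec`, and a binary outcome from
#' `plogis(intercept + sum_j beta_j * x_j)` where the named coefficients in
#' `spec$outcome_link$beta` refer to predictor columns. Used to validate
#' odds-ratio recovery of the regression stage against known truth.
#'
#' @param spec A [demographic_spec()] whose `outcome_link` is set.
#' @param n Number of persons.
#' @param prevalence Named numeric vector: Bernoulli prevalence of each binary
#'   predictor named in `beta`.
#' @param seed Integer seed.
#' @return A tibble with `person_id`, demographics, the predictor columns and
#'   an integer `outcome` column.
#' @export
generate_regression_cohort <- function(spec, n, prevalence, seed = NULL) {
  stopifnot(inherits(spec, "demographic_spec"))
  link <- spec$outcome_link
  if (is.null(link)) stop("spec$outcome_link must be supplied", call. = FALSE)
  beta <- link$beta %||% numeric()
  if (length(beta) > 0 &&
      (is.null(names(beta)) || !all(names(beta) %in% names(prevalence)))) {
    stop("every coefficient in beta needs a prevalence entry", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  preds <- names(prevalence)
  X <- vapply(preds, function(v) stats::rbinom(n, 1L, prevalence[[v]]),
              integer(n))
  X <- matrix(X, nrow = n, dimnames = list(NULL, preds))
  eta <- rep(link$intercept %||% 0, n)
  for (v in names(beta)) eta <- eta + beta[[v]] * X[, v]
  outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  draw <- function(v) {
    sample(DEMOGRAPHIC_LEVELS[[v]], n, replace = TRUE, prob = spec[[v]])
  }
  out <- tibble::tibble(
    person_id = sprintf("P%06d", seq_len(n)),
    gender = factor(draw("gender"), DEMOGRAPHIC_LEVELS$gender),
    age_group = factor(draw("age_group"), DEMOGRAPHIC_LEVELS$age_group),
    income_q = factor(draw("income_q"), DEMOGRAPHIC_LEVELS$income_q),
    education = factor(draw("education"), DEMOGRAPHIC_LEVELS$education)
  )
  dplyr::bind_cols(out, tibble::as_tibble(X), tibble::tibble(outcome = outcome))
}
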