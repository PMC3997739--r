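#' Build feature specifications for a maximum-entropy model
#'
#' Feature classes are enabled by presence sample size `m` following the
#' conventional presence-background defaults: linear always; quadratic
#' from 10; hinge from 15; product (pairwise interactions) from 80.  All
#' features are rescaled to `[0, 1]` using the background range of each
#' variable, with clamping outside that range at prediction time.  Hinge
#' knots sit at the background deciles (10%..90%).  Constant variables
#' contribute no features and raise a warning.
#'
#' @param background data.frame of background variable values (one column
#'   per candidate variable) used for scaling ranges and hinge knots
#' @param m presence sample size driving class selection (>= 2)
#' @param classes optional explicit character vector overriding the
#'   sample-size rule (subset of `linear`, `quadratic`, `product`, `hinge`)
#' @param n_hinge number of hinge knots per variable (default 9, at deciles)
#' @return list of feature specs, class `chs_features`; each spec has
#'   `var`, `class`, `min`, `max`, and optionally `knot` / `partner`
#' @export
build_features <- function(background, m, classes = NULL, n_hinge = 9) {
  if (m < 2) stop("need at least 2 presence records")
  background <- as.data.frame(background)
  if (is.null(classes)) {
    classes <- "linear"
    if (m >= 10) classes <- c(classes, "quadratic")
    if (m >= 15) classes <- c(classes, "hinge")
    if (m >= 80) classes <- c(classes, "product")
  }
  vars <- names(background)
  rng <- lapply(background, range, na.rm = TRUE)
  const <- vapply(vars, function(v) rng[[v]][1] == rng[[v]][2], logical(1))
  if (any(const)) {
    warning("constant layers dropped from features: ",
            paste(vars[const], collapse = ", "))
    vars <- vars[!const]
  }
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  for (v in vars) {
    lo <- rng[[v]][1]; hi <- rng[[v]][2]
    if ("linear" %in% classes) {
      add(list(var = v, class = "linear", min = lo, max = hi))
    }
    if ("quadratic" %in% classes) {
      add(list(var = v, class = "quadratic", min = lo, max = hi))
    }
    if ("hinge" %in% classes && n_hinge > 0) {
      knots <- unique(stats::quantile(background[[v]],
                                      probs = seq_len(n_hinge) / (n_hinge + 1),
                                      na.rm = TRUE, names = FALSE))
      for (kn in knots[knots < hi]) {
        add(list(var = v, class = "hinge", min = lo, max = hi, knot = kn))
      }
    }
  }
  if ("product" %in% classes && length(vars) >= 2) {
    for (a in seq_len(length(vars) - 1L)) {
      for (b in (a + 1L):length(vars)) {
        add(list(var = vars[a], class = "product",
                 min = rng[[vars[a]]][1], max = rng[[vars[a]]][2],
                 partner = vars[b],
                 pmin = rng[[vars[b]]][1], pmax = rng[[vars[b]]][2]))
      }
    }
  }
  structure(specs, class = "chs_features", variables = vars)
}

#' Evaluate features on environmental data
#'
#' @param features `chs_features` from [build_features()]
#' @param env data.frame with one column per variable named in the specs
#' @param clamp clamp scaled values into `[0, 1]` outside the background
#'   range (default TRUE)
#' @return numeric matrix, one column per feature, values in `[0, 1]`
#'   on (and, with clamping, off) the background
#' @export
feature_matrix <- function(features, env, clamp = TRUE) {
  env <- as.data.frame(env)
  scale01 <- function(v, lo, hi) {
    s <- (v - lo) / (hi - lo)
    if (clamp) s <- pmin(pmax(s, 0), 1)
    s
  }
  cols <- lapply(features, function(f) {
    v <- env[[f$var]]
    if (is.null(v)) stop("env lacks variable: ", f$var)
    switch(f$class,
      linear = scale01(v, f$min, f$max),
      quadratic = scale01(v, f$min, f$max)^2,
      hinge = {
        h <- (v - f$knot) / (f$max - f$knot)
        h <- pmax(h, 0)
        if (clamp) h <- pmin(h, 1)
        h
      },
      product = scale01(v, f$min, f$max) *
        scale01(env[[f$partner]], f$pmin, f$pmax),
      stop("unknown feature class: ", f$class)
    )
  })
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(features, function(f) {
    switch(f$class,
           linear = f$var,
           quadratic = paste0(f$var, "^2"),
           hinge = sprintf("h(%s@%.4g)", f$var, f$knot),
           product = paste0(f$var, "*", f$partner))
  }, character(1))
  m
}

# Regularization scale c(m) per feature class: published default tables
# interpolated over presence sample size, divided by sqrt(m).
beta_scale <- function(class, m) {
  tab <- switch(class,
    hinge = list(x = c(0, 1), y = c(0.5, 0.5)),
    # linear/quadratic/product share one table
    list(x = c(0, 10, 17, 30, 100), y = c(1, 1, 0.2, 0.2, 0.05))
  )
  stats::approx(tab$x, tab$y, xout = min(m, max(tab$x)), rule = 2)$y / sqrt(m)
}

#' Fit a regularized maximum-entropy presence-background model
#'
#' Fits the Gibbs distribution `q(x) = exp(sum_j lambda_j f_j(x)) / Z`
#' over the background by minimizing the L1-regularized negative average
#' presence log-likelihood with cyclic coordinate descent (per-coordinate
#' Newton step with soft-thresholding and step halving, so the objective
#' never increases).  Iteration stops when one full sweep improves the
#' regularized objective by less than `convergence`, or at
#' `max_iterations` sweeps.  At convergence the solution satisfies the
#' defining moment condition `|E_q[f_j] - mean_presence(f_j)| <= beta_j`
#' (with equality where `lambda_j != 0`).
#'
#' Default per-feature regularization is
#' `beta_j = reg_multiplier * sd_presence(f_j) * c(m)` with `c(m)` an
#' interpolated table by feature class and presence count; pass `beta`
#' explicitly (scalar or per-feature) to override.
#'
#' @param X_pres feature matrix at presence sites (rows = presences)
#' @param X_bg feature matrix over the background (presence cells should
#'   be merged into the background)
#' @param features optional `chs_features` stored with the model
#' @param beta optional explicit regularization (scalar or per-feature)
#' @param reg_multiplier multiplier on the default betas (default 1)
#' @param convergence stop when a sweep improves the objective by less
#'   than this (default 1e-5)
#' @param max_iterations maximum coordinate-descent sweeps (default 500)
#' @return object of class `chs_maxent`: `lambda`, `beta`, `features`,
#'   `logZ`, `H` (entropy of the fitted distribution over the background,
#'   nats), `gain` (regularized training gain, nats), `n_bg`,
#'   `iterations`, `converged`, `objective`
#' @export
fit_maxent <- function(X_pres, X_bg, features = NULL, beta = NULL,
                       reg_multiplier = 1, convergence = 1e-5,
                       max_iterations = 500) {
  X_pres <- as.matrix(X_pres); X_bg <- as.matrix(X_bg)
  if (nrow(X_pres) < 2L) stop("need at least 2 presence records")
  if (!all(is.finite(X_pres)) || !all(is.finite(X_bg))) {
    stop("non-finite feature values")
  }
  p <- ncol(X_bg); n <- nrow(X_bg); m <- nrow(X_pres)
  fbar <- colMeans(X_pres)
  if (is.null(beta)) {
    cls <- if (is.null(features)) rep("linear", p)
    else vapply(features, `[[`, character(1), "class")
    sdp <- apply(X_pres, 2, stats::sd)
    sdp <- pmax(sdp, 1e-4)  # floor: a feature constant over presences
                            # still gets a little regularization
    beta <- reg_multiplier * sdp *
      vapply(cls, beta_scale, numeric(1), m = m)
  } else {
    beta <- rep_len(beta, p) * 1  # scalar or per-feature
  }
  if (any(beta < 0)) stop("beta must be non-negative")

  lambda <- numeric(p)
  eta <- numeric(n)              # X_bg %*% lambda
  lse <- function(e) { mx <- max(e); mx + log(sum(exp(e - mx))) }
  logZ <- lse(eta)
  obj <- function(lz, lam) lz - sum(lam * fbar) + sum(beta * abs(lam))
  J <- obj(logZ, lambda)
  trace <- J
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    J_sweep <- J
    q <- exp(eta - logZ)
    for (j in seq_len(p)) {
      xj <- X_bg[, j]
      Eq <- sum(q * xj)
      g <- Eq - fbar[j]
      h <- sum(q * xj * xj) - Eq^2
      if (h < 1e-12) h <- 1e-12
      z <- lambda[j] - g / h
      new <- sign(z) * max(abs(z) - beta[j] / h, 0)
      delta <- new - lambda[j]
      if (delta == 0) next
      if (abs(delta) > 10) delta <- sign(delta) * 10
      # step halving: guarantee the regularized objective never increases
      repeat {
        eta_try <- eta + delta * xj
        lz_try <- lse(eta_try)
        lam_try <- lambda
        lam_try[j] <- lambda[j] + delta
        J_try <- obj(lz_try, lam_try)
        if (J_try <= J + 1e-12 || abs(delta) < 1e-12) break
        delta <- delta / 2
      }
      if (J_try <= J + 1e-12) {
        lambda[j] <- lambda[j] + delta
        eta <- eta_try
        logZ <- lz_try
        J <- J_try
        q <- exp(eta - logZ)
      }
    }
    trace <- c(trace, J)
    if (J_sweep - J < convergence) { converged <- TRUE; break }
  }
  if (J > trace[1] + 1e-8) {
    stop("maxent optimization diverged (objective increased); ",
         "final objective ", J, " vs initial ", trace[1])
  }
  q <- exp(eta - logZ)
  H <- -sum(q * ifelse(q > 0, log(q), 0))
  gain <- log(n) - J
  structure(list(
    lambda = stats::setNames(lambda, colnames(X_bg)),
    beta = stats::setNames(beta, colnames(X_bg)),
    features = features, logZ = logZ, H = H, gain = gain,
    n_bg = n, m = m, fbar = fbar,
    iterations = it, converged = converged, objective = trace
  ), class = "chs_maxent")
}

#' @export
print.chs_maxent <- function(x, ...) {
  cat(sprintf(
    "<chs_maxent> %d features (%d active), n_bg=%d, m=%d\n  gain=%.4f nats, H=%.4f, %d sweeps%s\n",
    length(x$lambda), sum(x$lambda != 0), x$n_bg, x$m, x$gain, x$H,
    x$iterations, if (x$converged) " (converged)" else " (iteration cap)"))
  invisible(x)
}

#' Logistic habitat suitability index
#'
#' Maps the fitted Gibbs density to a habitat suitability index in
#' `[0, 1]` via `HSI = e^H q(x) / (1 + e^H q(x))`, with `H` the entropy
#' of the fitted distribution over the background.  Under the null model
#' (all weights zero) `q = 1/N` and `H = log N`, so the HSI is exactly
#' 0.5 everywhere: 0.5 marks "typical" presence conditions.
#'
#' @param model `chs_maxent`
#' @param X feature matrix (same columns the model was fitted with)
#' @return numeric vector of HSI values in `[0, 1]`
#' @export
logistic_output <- function(model, X) {
  X <- as.matrix(X)
  logq <- drop(X %*% model$lambda) - model$logZ
  eHq <- exp(model$H + logq)
  eHq / (1 + eHq)
}

#' @export
#' @rdname logistic_output
#' @param object,newdata,type standard predict arguments; `type` one of
#'   `"hsi"` (logistic output), `"raw"` (normalized `q`), `"exp"`
#'   (`e^H q`)
#' @param ... unused
predict.chs_maxent <- function(object, newdata,
                               type = c("hsi", "raw", "exp"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata) || !is.null(dim(newdata)) &&
           is.null(object$features)) as.matrix(newdata)
  else if (!is.null(object$features) && is.data.frame(newdata)) {
    feature_matrix(object$features, newdata)
  } else as.matrix(newdata)
  logq <- drop(X %*% object$lambda) - object$logZ
  switch(type,
         raw = exp(logq),
         exp = exp(object$H + logq),
         hsi = { e <- exp(object$H + logq); e / (1 + e) })
}

#' Regularized training gain
#'
#' `gain = mean_presence log(q(x) N_bg) - sum_j beta_j |lambda_j|`: the
#' improvement in average presence log-likelihood over the uniform null
#' model, minus the L1 penalty.  The null model scores exactly 0.
#'
#' @param model `chs_maxent`
#' @param X_pres presence feature matrix (defaults to the training
#'   moments stored in the model)
#' @return gain in nats
#' @export
training_gain <- function(model, X_pres = NULL) {
  if (is.null(X_pres)) return(model$gain)
  X_pres <- as.matrix(X_pres)
  mean(drop(X_pres %*% model$lambda) - model$logZ + log(model$n_bg)) -
    sum(model$beta * abs(model$lambda))
}

#' Jack-knife variable importance
#'
#' For each variable `v`, fits (a) the model on all variables except `v`
#' and (b) the model on `v` alone, reporting the regularized training
#' gain of both and, when an evaluation split is supplied, the held-out
#' AUC of the with-only model.  High with-only gain and a large gain drop
#' when the variable is withheld both indicate importance; the two views
#' disagree when variables covary.
#'
#' @param pres_env data.frame of variable values at training presences
#' @param bg_env data.frame of variable values over the background
#' @param test_pres_env optional data.frame at held-out presences (enables
#'   the with-only test AUC column)
#' @param variables which variables to assess (default: all columns)
#' @param reg_multiplier,convergence,max_iterations passed to [fit_maxent()]
#' @return data.frame: `variable`, `gain_without`, `gain_with_only`,
#'   `auc_with_only` (NA without an evaluation split), plus a `full_gain`
#'   attribute; rows sorted by decreasing `gain_with_only`
#' @export
jackknife_importance <- function(pres_env, bg_env, test_pres_env = NULL,
                                 variables = NULL, reg_multiplier = 1,
                                 convergence = 1e-5, max_iterations = 500) {
  pres_env <- as.data.frame(pres_env); bg_env <- as.data.frame(bg_env)
  if (is.null(variables)) variables <- names(bg_env)
  if (length(variables) < 1L) stop("need at least 1 variable")
  m <- nrow(pres_env)
  fit_on <- function(vars) {
    fe <- build_features(bg_env[, vars, drop = FALSE], m)
    if (!length(fe)) return(NULL)
    fit_maxent(feature_matrix(fe, pres_env[, vars, drop = FALSE]),
               feature_matrix(fe, bg_env[, vars, drop = FALSE]),
               features = fe, reg_multiplier = reg_multiplier,
               convergence = convergence, max_iterations = max_iterations)
  }
  full <- fit_on(variables)
  rows <- lapply(variables, function(v) {
    rest <- setdiff(variables, v)
    m_wo <- if (length(rest)) fit_on(rest) else NULL
    m_only <- fit_on(v)
    auc <- NA_real_
    if (!is.null(test_pres_env) && !is.null(m_only)) {
      sp <- predict(m_only, test_pres_env[, v, drop = FALSE], type = "raw")
      sb <- predict(m_only, bg_env[, v, drop = FALSE], type = "raw")
      auc <- auc_presence_background(sp, sb)
    }
    data.frame(variable = v,
               gain_without = if (is.null(m_wo)) 0 else m_wo$gain,
               gain_with_only = if (is.null(m_only)) NA_real_ else m_only$gain,
               auc_with_only = auc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$gain_with_only), ]
  rownames(out) <- NULL
  attr(out, "full_gain") <- if (is.null(full)) NA_real_ else full$gain
  out
}
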