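#' Multinomial log-likelihood of an MPT model
#'
#' Log-likelihood kernel \eqn{\sum_c n_c \ln p_c} (no multinomial
#' coefficient), summed over conditions for joint models, with the
#' convention \eqn{0 \ln 0 = 0}. A category with zero predicted probability
#' but a positive count yields `-Inf` rather than an error.
#'
#' @param object An [mpt_tree()] or [joint_model()].
#' @param params Named vector of qualified parameter values in \eqn{[0,1]}.
#' @param counts Observed category counts; a numeric vector for a single
#'   tree, or a matrix / named list with one row or element per condition.
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
loglik_mpt <- function(object, params, counts) {
  model <- if (inherits(object, "mpt_tree")) {
    joint_model(list(condition = object))
  } else object
  stopifnot(inherits(model, "mpt_joint"))
  cts <- .canon_counts(model, counts)
  ll <- 0
  for (cond in names(model$trees)) {
    p <- category_probs(model$trees[[cond]], params)
    n <- cts[[cond]]
    term <- ifelse(n > 0, n * log(p), 0)
    ll <- ll + sum(term)
  }
  ll
}

.canon_counts <- function(model, counts) {
  conds <- names(model$trees)
  if (is.numeric(counts) && is.null(dim(counts))) {
    if (length(conds) != 1L) {
      stop("a plain vector of counts fits a single-condition model only")
    }
    counts <- stats::setNames(list(unname(counts)), conds)
  } else if (is.matrix(counts) || is.data.frame(counts)) {
    m <- as.matrix(counts)
    if (is.null(rownames(m))) {
      if (nrow(m) != length(conds)) stop("count rows do not match conditions")
      rownames(m) <- conds
    }
    counts <- stats::setNames(lapply(conds, function(cc) {
      if (!cc %in% rownames(m)) stop("no counts for condition: ", cc)
      unname(m[cc, ])
    }), conds)
  } else if (is.list(counts)) {
    absent <- setdiff(conds, names(counts))
    if (length(absent)) {
      stop("no counts for condition(s): ", paste(absent, collapse = ", "))
    }
    counts <- lapply(counts[conds], unname)
  } else stop("unsupported counts format")
  for (cc in conds) {
    n <- counts[[cc]]
    ncat <- length(model$trees[[cc]]$categories)
    if (length(n) != ncat) {
      stop("condition ", cc, ": expected ", ncat, " category counts")
    }
    if (anyNA(n) || any(n < 0) || any(abs(n - round(n)) > 1e-8)) {
      stop("condition ", cc, ": counts must be nonnegative integers")
    }
    counts[[cc]] <- round(n)
  }
  counts
}

# Sufficient statistics: for each qualified parameter j,
# A_j = sum over cells of n * (exponent of theta_j),
# B_j = sum over cells of n * (exponent of 1 - theta_j).
# The product-branch structure makes the log-likelihood
#   sum_j A_j log theta_j + B_j log(1 - theta_j),
# i.e. fully separable in the qualified parameters.
.suff_stats <- function(model, cts) {
  pars <- model$parameters
  A <- B <- stats::setNames(numeric(length(pars)), pars)
  for (cond in names(model$trees)) {
    tr <- model$trees[[cond]]
    n <- cts[[cond]]
    A[tr$parameters] <- A[tr$parameters] + as.vector(crossprod(tr$a, n))
    B[tr$parameters] <- B[tr$parameters] + as.vector(crossprod(tr$b, n))
  }
  list(A = A, B = B)
}

.binom_ll <- function(theta, A, B) {
  sum(ifelse(A > 0, A * log(theta), 0) + ifelse(B > 0, B * log1p(-theta), 0))
}

#' Maximum-likelihood fit of an MPT model
#'
#' Fits a single tree or a [joint_model()] by maximizing the multinomial
#' likelihood subject to the model's restrictions.
#'
#' For models whose restrictions are all equalities the MLE has a closed
#' form: the branch-product structure separates the log-likelihood by
#' parameter, so each (pooled) parameter is estimated as
#' \eqn{\hat\theta = A/(A+B)}, where \eqn{A} and \eqn{B} count, over all
#' cells, how often the parameter and its complement enter the observed
#' branches. For the saturated baseline tree this reduces to
#' \eqn{\hat{ci} = n_1/N}, \eqn{\hat{psc} = n_2/(N-n_1)},
#' \eqn{\hat{prr} = n_3/(N-n_1-n_2)}. Difference restrictions couple
#' parameters and are fitted numerically: quasi-Newton (BFGS) with analytic
#' gradients on logit-transformed probabilities, the shared difference
#' optimized on its natural scale with \eqn{b + \Delta} projected into
#' \eqn{[0,1]}, and seeded random restarts. `method = "optim"` forces the
#' numeric route even where the closed form applies (used as an internal
#' cross-check).
#'
#' A parameter whose branches receive zero observations (e.g. `psc` when
#' every response is correct) is non-identifiable; it is reported as `NA`
#' and listed in `$undefined` rather than raising an error.
#'
#' @param model An [mpt_tree()] or [joint_model()].
#' @param counts See [loglik_mpt()]. Every condition must have a positive
#'   total.
#' @param method `"auto"` (closed form where available), `"closed_form"`,
#'   or `"optim"`.
#' @param n_restarts Number of optimizer starts (first start is
#'   data-driven, the rest random); ties in final log-likelihood are broken
#'   toward the lowest restart index.
#' @param seed Integer seed for the restart draws (local RNG; the caller's
#'   RNG state is untouched).
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return An object of class `mpt_fit` with elements `estimates` (named,
#'   `NA` where non-identifiable), `log_likelihood`, `g_squared`, `df`,
#'   `converged`, `n_restarts_used`, `undefined`, `method`, `n_total`.
#' @examples
#' fit <- fit_mpt(baseline_tree(), c(70, 15, 10, 5))
#' fit$estimates  # ci = .70, psc = .50, prr = 2/3
#' @export
fit_mpt <- function(model, counts, method = c("auto", "closed_form", "optim"),
                    n_restarts = 10L, seed = 1L, reltol = 1e-12) {
  method <- match.arg(method)
  if (inherits(model, "mpt_tree")) model <- joint_model(list(condition = model))
  stopifnot(inherits(model, "mpt_joint"))
  cts <- .canon_counts(model, counts)
  if (any(vapply(cts, sum, numeric(1)) <= 0)) {
    stop("every condition must have a positive total count")
  }
  st <- .model_structure(model)
  ss <- .suff_stats(model, cts)
  # pool sufficient statistics over equality classes (representative space)
  Ar <- tapply(ss$A, st$rep[names(ss$A)], sum)
  Br <- tapply(ss$B, st$rep[names(ss$B)], sum)
  Ar <- Ar[st$reps]; Br <- Br[st$reps]

  has_diff <- length(st$deltas) > 0L
  if (method == "closed_form" && has_diff) {
    stop("no closed form under difference restrictions; use method = 'optim'")
  }
  use_closed <- method == "closed_form" || (method == "auto" && !has_diff)

  if (use_closed) {
    theta_rep <- as.numeric(Ar) / (Ar + Br)
    names(theta_rep) <- st$reps
    undefined_rep <- st$reps[Ar + Br == 0]
    theta_rep[undefined_rep] <- 0.5   # arbitrary; carries no likelihood mass
    converged <- TRUE; n_used <- 0L
  } else {
    opt <- .fit_numeric(st, Ar, Br, n_restarts = n_restarts, seed = seed,
                        reltol = reltol)
    theta_rep <- opt$theta_rep
    undefined_rep <- st$reps[Ar + Br == 0 & !(st$reps %in% st$derived)]
    converged <- opt$converged; n_used <- opt$n_restarts_used
  }

  full <- stats::setNames(theta_rep[st$rep], names(st$rep))
  gof <- .goodness_of_fit(model, full, cts)
  estimates <- full
  estimates[st$rep %in% undefined_rep] <- NA_real_

  structure(list(
    estimates = estimates,
    log_likelihood = gof$loglik,
    g_squared = gof$g_squared,
    df = sum(vapply(model$trees, function(t) length(t$categories) - 1L,
                    integer(1))) - st$n_free,
    converged = converged,
    n_restarts_used = n_used,
    undefined = names(estimates)[is.na(estimates)],
    method = if (use_closed) "closed_form" else "optim",
    n_total = sum(unlist(cts)),
    model = model, counts = cts
  ), class = "mpt_fit")
}

# Numeric ML under equality + difference restrictions.
# Free vector: logit(theta) for base representatives, then one raw delta per
# difference restriction. Analytic gradient; pure R, problems are tiny.
.fit_numeric <- function(st, Ar, Br, n_restarts, seed, reltol) {
  nb <- length(st$free_base); nd <- length(st$deltas)
  identifiable <- (Ar + Br)[st$free_base] > 0

  expand_rep <- function(u) {
    base <- stats::setNames(stats::plogis(u[seq_len(nb)]), st$free_base)
    base[!identifiable] <- 0.5
    th <- stats::setNames(rep(NA_real_, length(st$reps)), st$reps)
    th[st$free_base] <- base
    if (nd) for (i in seq_len(nd)) {
      d <- st$deltas[[i]]
      th[d$minuends] <- pmin(1, pmax(0, th[d$subtrahends] + u[nb + i]))
    }
    th
  }
  negll <- function(u) {
    th <- expand_rep(u)
    -.binom_ll(th[st$reps], Ar, Br)
  }
  grad <- function(u) {
    th <- expand_rep(u)
    # g_r = dL/dtheta_r for every representative
    g <- ifelse(Ar > 0, Ar / th[st$reps], 0) -
         ifelse(Br > 0, Br / (1 - th[st$reps]), 0)
    names(g) <- st$reps
    gu <- numeric(nb + nd)
    carry <- stats::setNames(numeric(nb), st$free_base)
    if (nd) for (i in seq_len(nd)) {
      d <- st$deltas[[i]]
      inside <- th[d$subtrahends] + u[nb + i]
      open <- inside > 0 & inside < 1          # projection active -> zero grad
      gm <- ifelse(open, g[d$minuends], 0)
      carry[d$subtrahends] <- carry[d$subtrahends] + gm
      gu[nb + i] <- -sum(gm)
    }
    thb <- th[st$free_base]
    gu[seq_len(nb)] <- -(g[st$free_base] + carry) * thb * (1 - thb)
    gu[seq_len(nb)][!identifiable] <- 0
    gu
  }

  # data-driven start: per-representative pooled estimates, moderate clamp
  sat <- as.numeric(Ar) / pmax(Ar + Br, 1)
  names(sat) <- st$reps
  start1 <- stats::qlogis(pmin(0.98, pmax(0.02, sat[st$free_base])))
  d1 <- if (nd) vapply(st$deltas, function(d) {
    mean(pmin(0.9, pmax(-0.9, sat[d$minuends] - sat[d$subtrahends])))
  }, numeric(1)) else numeric(0)

  starts <- vector("list", max(1L, n_restarts))
  starts[[1]] <- c(start1, d1)
  if (n_restarts > 1L) {
    draws <- .with_seed(seed, {
      lapply(seq_len(n_restarts - 1L), function(i) {
        c(stats::qlogis(stats::runif(nb, 0.05, 0.95)),
          if (nd) stats::runif(nd, -0.5, 0.5) else numeric(0))
      })
    })
    starts[seq_len(n_restarts - 1L) + 1L] <- draws
  }

  best <- NULL
  for (i in seq_along(starts)) {
    res <- tryCatch(
      stats::optim(starts[[i]], negll, grad, method = "BFGS",
                   control = list(maxit = 500, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    res$par <- .newton_polish(res$par, negll, grad)
    res$value <- negll(res$par)
    if (is.null(best) || res$value < best$value - 1e-12) {
      best <- res; best$restart <- i
    }
  }
  if (is.null(best)) stop("optimizer failed in every restart")
  list(theta_rep = expand_rep(best$par),
       converged = best$convergence == 0,
       n_restarts_used = length(starts))
}

# Newton refinement of an optim() solution. Quasi-Newton stops when the
# relative improvement is tiny, which can leave parameter errors around
# 1e-5; a few damped Newton steps on the analytic gradient reach gradient
# norms near machine precision. A small ridge keeps the numeric Hessian
# solvable along non-identifiable (zero-information) directions.
.newton_polish <- function(u, negll, grad, max_iter = 40L) {
  f <- negll(u)
  for (it in seq_len(max_iter)) {
    g <- grad(u)
    if (!all(is.finite(g)) || max(abs(g)) < 1e-10) break
    H <- tryCatch(stats::optimHess(u, negll, grad), error = function(e) NULL)
    if (is.null(H) || !all(is.finite(H))) break
    step <- tryCatch(solve(H + diag(1e-10, length(u)), g),
                     error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    moved <- FALSE
    for (damp in c(1, 0.5, 0.25, 0.1)) {
      u_new <- u - damp * step
      f_new <- negll(u_new)
      if (is.finite(f_new) && f_new <= f) {
        u <- u_new; f <- f_new; moved <- TRUE
        break
      }
    }
    if (!moved) break
  }
  u
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Log-likelihood and G^2 = 2 sum n log(n / (N_c p_hat)) of fitted values.
.goodness_of_fit <- function(model, full_params, cts) {
  ll <- 0; g2 <- 0
  for (cond in names(model$trees)) {
    p <- category_probs(model$trees[[cond]], full_params)
    n <- cts[[cond]]; N <- sum(n)
    pos <- n > 0
    ll <- ll + sum(n[pos] * log(p[pos]))
    g2 <- g2 + 2 * sum(n[pos] * log(n[pos] / (N * p[pos])))
  }
  list(loglik = ll, g_squared = max(0, g2))
}

#' @export
print.mpt_fit <- function(x, digits = 4, ...) {
  cat("MPT maximum-likelihood fit (", x$method, ")\n", sep = "")
  cat("  log-likelihood:", format(x$log_likelihood, digits = digits),
      "  G2:", format(x$g_squared, digits = digits),
      "  df:", x$df, "\n")
  est <- format(round(x$estimates, digits))
  cat("  estimates:\n")
  for (nm in names(est)) cat("    ", nm, "=", est[[nm]], "\n")
  if (length(x$undefined)) {
    cat("  non-identifiable:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
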