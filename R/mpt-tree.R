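#' Multinomial processing tree with product-form branches
#'
#' Constructs a rooted processing tree in which each response category is
#' reached by a single branch, and each branch probability is a product of
#' parameters \eqn{\theta} and complements \eqn{1 - \theta}. This covers the
#' baseline model for probe responses in four-alternative identification
#' tasks (see [baseline_tree()]) and any reparameterization of it.
#'
#' Branches are given as character vectors of factors, e.g.
#' `c("1-ci", "psc")` for \eqn{(1-ci)\,psc}. Every parameter referenced in a
#' branch must appear in `parameters`. At construction the tree is checked
#' numerically: for random parameter vectors in \eqn{[0,1]^k} the category
#' probabilities must be in \eqn{[0,1]} and sum to 1 within `1e-12`.
#'
#' @param branches Named list, one element per response category, each a
#'   character vector of factors (`"theta"` or `"1-theta"`).
#' @param parameters Character vector of parameter names in order. Defaults
#'   to the parameters referenced by `branches`, in order of appearance.
#' @param check Logical; verify the normalization invariant numerically.
#' @return An object of class `mpt_tree`.
#' @examples
#' tr <- baseline_tree()
#' category_probs(tr, c(ci = 0.5, psc = 0.5, prr = 0.5))
#' @export
mpt_tree <- function(branches, parameters = NULL, check = TRUE) {
  if (is.null(names(branches)) || anyNA(names(branches)) ||
      any(names(branches) == "")) {
    stop("every branch must be named after its response category")
  }
  parsed <- lapply(branches, .parse_factors)
  referenced <- unique(unlist(lapply(parsed, function(f) f$param)))
  if (is.null(parameters)) parameters <- referenced
  missing_par <- setdiff(referenced, parameters)
  if (length(missing_par)) {
    stop("branch references undeclared parameter(s): ",
         paste(missing_par, collapse = ", "))
  }
  k <- length(parameters)
  n_cat <- length(branches)
  # exponent matrices: a[c, j] copies of theta_j, b[c, j] copies of 1-theta_j
  a <- b <- matrix(0L, n_cat, k, dimnames = list(names(branches), parameters))
  for (cc in seq_len(n_cat)) {
    f <- parsed[[cc]]
    for (i in seq_along(f$param)) {
      j <- match(f$param[i], parameters)
      if (f$complement[i]) b[cc, j] <- b[cc, j] + 1L else a[cc, j] <- a[cc, j] + 1L
    }
  }
  tree <- structure(
    list(categories = names(branches), parameters = parameters,
         branches = branches, a = a, b = b),
    class = "mpt_tree"
  )
  if (check) .check_tree_normalization(tree)
  tree
}

.parse_factors <- function(fac) {
  fac <- gsub("[[:space:]()]", "", as.character(fac))
  complement <- startsWith(fac, "1-")
  param <- ifelse(complement, substring(fac, 3L), fac)
  if (any(param == "")) stop("empty factor in branch definition")
  list(param = param, complement = complement)
}

.check_tree_normalization <- function(tree, n_draws = 25L) {
  k <- length(tree$parameters)
  # deterministic probe points: corners, center, and a low-discrepancy fill
  probes <- rbind(
    matrix(0, 1, k), matrix(1, 1, k), matrix(0.5, 1, k),
    outer(seq_len(n_draws), seq_len(k), function(i, j) {
      (i * (j * 2 - 1) * 0.6180339887498949) %% 1
    })
  )
  for (r in seq_len(nrow(probes))) {
    th <- stats::setNames(probes[r, ], tree$parameters)
    p <- category_probs(tree, th)
    if (any(p < -1e-12 | p > 1 + 1e-12) || abs(sum(p) - 1) > 1e-12) {
      stop("branch probabilities do not form a distribution; ",
           "the tree is not a complete binary processing tree")
    }
  }
  invisible(tree)
}

#' Baseline processing tree for probe responses
#'
#' The baseline model for the probe response in ignored-repetition and
#' control trials of a four-alternative identification task. The probe
#' target is identified correctly with probability `ci`; otherwise the
#' probe-distractor response is given with conditional probability `psc`;
#' otherwise the former prime response is retrieved and executed with
#' conditional probability `prr`; otherwise the remaining fourth response
#' is given.
#'
#' @param label Optional condition label; parameter names are qualified as
#'   `"ci@label"` etc., so trees for several conditions can share a joint
#'   model without name clashes.
#' @return An `mpt_tree` with categories `correct`, `distractor_error`,
#'   `prime_response_error`, `other_error`.
#' @export
baseline_tree <- function(label = NULL) {
  q <- function(p) if (is.null(label)) p else paste0(p, "@", label)
  ci <- q("ci"); psc <- q("psc"); prr <- q("prr")
  mpt_tree(
    branches = list(
      correct              = ci,
      distractor_error     = c(paste0("1-", ci), psc),
      prime_response_error = c(paste0("1-", ci), paste0("1-", psc), prr),
      other_error          = c(paste0("1-", ci), paste0("1-", psc), paste0("1-", prr))
    ),
    parameters = c(ci, psc, prr),
    check = FALSE
  )
}

#' Category probabilities of a processing tree
#'
#' @param tree An [mpt_tree()].
#' @param params Named numeric vector covering `tree$parameters`, all values
#'   in \eqn{[0, 1]}.
#' @return Named numeric vector of category probabilities (sums to 1).
#' @export
category_probs <- function(tree, params) {
  stopifnot(inherits(tree, "mpt_tree"))
  th <- .bind_params(params, tree$parameters)
  # p_c = prod_j theta_j^a_cj (1-theta_j)^b_cj ; 0^0 = 1 by convention
  lt <- ifelse(tree$a > 0, tree$a * log(.col_rep(th, tree$a)), 0) +
        ifelse(tree$b > 0, tree$b * log(.col_rep(1 - th, tree$b)), 0)
  p <- exp(rowSums(lt))
  # exact zeros: log() above gives -Inf -> exp gives 0, but guard NaN (0*-Inf)
  nan <- is.nan(p)
  if (any(nan)) {
    for (cc in which(nan)) {
      p[cc] <- prod(th^tree$a[cc, ] * (1 - th)^tree$b[cc, ])
    }
  }
  stats::setNames(p, tree$categories)
}

.col_rep <- function(th, m) matrix(th, nrow(m), ncol(m), byrow = TRUE)

.bind_params <- function(params, needed) {
  if (is.null(names(params))) {
    if (length(params) == length(needed)) {
      names(params) <- needed
    } else {
      stop("unnamed parameter vector of wrong length")
    }
  }
  absent <- setdiff(needed, names(params))
  if (length(absent)) {
    stop("missing parameter value(s): ", paste(absent, collapse = ", "))
  }
  th <- params[needed]
  if (anyNA(th) || any(th < 0 | th > 1)) {
    stop("parameter values must lie in [0, 1]")
  }
  th
}

#' @export
print.mpt_tree <- function(x, ...) {
  cat("MPT tree:", length(x$categories), "categories,",
      length(x$parameters), "parameters\n")
  for (cc in x$categories) {
    cat("  ", format(cc, width = max(nchar(x$categories))), " = ",
        paste(x$branches[[cc]], collapse = " * "), "\n", sep = "")
  }
  invisible(x)
}
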