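#' Joint multi-condition MPT model
#'
#' Combines per-condition processing trees into one model whose parameters
#' can be tied together by restrictions. Parameters of different conditions
#' must carry distinct (qualified) names, e.g. `"prr@IR:repeated"`.
#'
#' @param trees Named list of [mpt_tree()] objects; names are condition
#'   labels and must be unique.
#' @param restrictions List of restrictions built with [restrict_equal()] or
#'   [restrict_difference()].
#' @return Object of class `mpt_joint`.
#' @seealso [fit_mpt()], [mpt_test()]
#' @export
joint_model <- function(trees, restrictions = list()) {
  if (inherits(trees, "mpt_tree")) trees <- list(condition = trees)
  if (is.null(names(trees)) || anyDuplicated(names(trees))) {
    stop("condition trees must have unique names")
  }
  if (!all(vapply(trees, inherits, logical(1), "mpt_tree"))) {
    stop("all elements of `trees` must be mpt_tree objects")
  }
  all_par <- unlist(lapply(trees, `[[`, "parameters"), use.names = FALSE)
  if (anyDuplicated(all_par)) {
    stop("parameter names must be unique across condition trees; ",
         "qualify them, e.g. baseline_tree(label = ...)")
  }
  if (inherits(restrictions, "mpt_restriction")) restrictions <- list(restrictions)
  for (r in restrictions) {
    if (!inherits(r, "mpt_restriction")) stop("invalid restriction object")
    bad <- setdiff(unlist(r[c("targets", "pairs")]), all_par)
    if (length(bad)) {
      stop("restriction references unknown parameter(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(trees = trees, restrictions = restrictions,
                 parameters = all_par),
            class = "mpt_joint")
}

#' Equality restriction
#'
#' Forces two or more parameters to share one value, e.g.
#' `restrict_equal("prr@IR", "prr@C")` for the hypothesis that prime-response
#' retrieval is unaffected by distractor repetition.
#'
#' @param ... Parameter names (character), at least two, all distinct.
#' @return Object of class `mpt_restriction`.
#' @export
restrict_equal <- function(...) {
  targets <- as.character(c(...))
  if (length(targets) < 2 || anyDuplicated(targets)) {
    stop("an equality restriction needs at least two distinct parameters")
  }
  structure(list(kind = "equality", targets = targets),
            class = "mpt_restriction")
}

#' Difference-equality restriction
#'
#' Constrains two parameter differences to be equal:
#' \eqn{a_1 - b_1 = a_2 - b_2}. This is the reparameterized interaction
#' restriction: the retrieval effect `prr_IR - prr_C` is forced to be the
#' same in two context conditions, while its common size remains free.
#'
#' @param pair1,pair2 Character vectors `c(minuend, subtrahend)`.
#' @return Object of class `mpt_restriction`.
#' @export
restrict_difference <- function(pair1, pair2) {
  pairs <- list(pair1, pair2)
  if (!all(lengths(pairs) == 2L)) {
    stop("each pair must name exactly two parameters: c(minuend, subtrahend)")
  }
  all4 <- unlist(pairs)
  if (anyDuplicated(all4)) {
    stop("the four parameters of a difference restriction must be distinct")
  }
  structure(list(kind = "difference_equality", pairs = pairs),
            class = "mpt_restriction")
}

#' @export
print.mpt_restriction <- function(x, ...) {
  if (x$kind == "equality") {
    cat("restriction:", paste(x$targets, collapse = " = "), "\n")
  } else {
    cat("restriction:", x$pairs[[1]][1], "-", x$pairs[[1]][2], "=",
        x$pairs[[2]][1], "-", x$pairs[[2]][2], "\n")
  }
  invisible(x)
}

#' @export
print.mpt_joint <- function(x, ...) {
  cat("Joint MPT model:", length(x$trees), "condition(s),",
      length(x$parameters), "parameters,",
      length(x$restrictions), "restriction(s)\n")
  st <- .model_structure(x)
  cat("  free parameters after restrictions:", st$n_free, "\n")
  for (r in x$restrictions) print(r)
  invisible(x)
}

# Resolve the free-parameter structure of a joint model.
#
# Equality restrictions are collapsed by union-find into representative
# parameters. Each difference restriction keeps its two subtrahends free,
# adds one shared difference parameter delta, and derives the minuends as
# b + delta (projected into [0,1] during optimization).
#
# Returns: rep (named map param -> representative), free_base (reps that are
# directly optimized probabilities), deltas (list of difference restrictions
# in representative space), derived (minuend reps), n_free.
.model_structure <- function(model) {
  pars <- model$parameters
  parent <- stats::setNames(pars, pars)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (r in model$restrictions) {
    if (r$kind == "equality") {
      root <- find(r$targets[1])
      for (t in r$targets[-1]) parent[[find(t)]] <- root
    }
  }
  rep_map <- vapply(pars, find, character(1))
  reps <- unique(rep_map)

  deltas <- list(); derived <- character(0)
  for (r in model$restrictions) {
    if (r$kind != "difference_equality") next
    pr <- lapply(r$pairs, function(p) unname(rep_map[p]))
    mins <- c(pr[[1]][1], pr[[2]][1]); subs <- c(pr[[1]][2], pr[[2]][2])
    if (anyDuplicated(c(mins, subs))) {
      stop("difference restriction collapsed onto itself by equality ",
           "restrictions; the combined restrictions are degenerate")
    }
    if (any(mins %in% derived)) {
      stop("a parameter may be the minuend of at most one difference restriction")
    }
    deltas <- c(deltas, list(list(minuends = mins, subtrahends = subs)))
    derived <- c(derived, mins)
  }
  free_base <- setdiff(reps, derived)
  list(rep = rep_map, reps = reps, free_base = free_base, deltas = deltas,
       derived = derived,
       n_free = length(free_base) + length(deltas))
}

# Expand free parameters (base probabilities + deltas) to the full qualified
# parameter vector, applying equality classes and derived differences.
.expand_params <- function(st, base, delta) {
  vals <- stats::setNames(rep(NA_real_, length(st$reps)), st$reps)
  vals[st$free_base] <- base
  if (length(st$deltas)) {
    for (i in seq_along(st$deltas)) {
      d <- st$deltas[[i]]
      vals[d$minuends] <- pmin(1, pmax(0, vals[d$subtrahends] + delta[i]))
    }
  }
  stats::setNames(vals[st$rep], names(st$rep))
}
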