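#' Upper-tail chi-square p value for a G-squared statistic
#'
#' @param g_squared Nonnegative likelihood-ratio statistic.
#' @param df Positive integer degrees of freedom.
#' @return Upper-tail probability of the central chi-square distribution.
#' @examples
#' chi2_p_value(5.63, 1)   # ~ .02
#' @export
chi2_p_value <- function(g_squared, df) {
  if (any(df < 1)) stop("df must be a positive integer")
  if (any(!is.finite(g_squared)) || any(g_squared < 0)) {
    stop("g_squared must be finite and nonnegative")
  }
  stats::pchisq(g_squared, df = df, lower.tail = FALSE)
}

#' Cohen's w effect size for a chi-square family test
#'
#' \eqn{w = \sqrt{G^2 / N}}, where `n_total` is the total number of trials
#' entering the tested joint model.
#'
#' @param g_squared Nonnegative statistic.
#' @param n_total Positive total trial count.
#' @examples
#' cohens_w(12.56, 10176)  # ~ .04
#' @export
cohens_w <- function(g_squared, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(g_squared < 0)) stop("g_squared must be nonnegative")
  sqrt(g_squared / n_total)
}

#' Bonferroni-Holm step-down adjustment
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "holm"`; kept as a
#' named operation because adjusted p values are part of the reported test
#' battery. An empty input returns an empty vector.
#'
#' @param p_values Numeric vector of p values in \eqn{[0,1]}.
#' @export
holm_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Signal-detection sensitivity d'
#'
#' \eqn{d' = z(\mathrm{hit}) - z(\mathrm{fa})}. Extreme rates (0 or 1) make
#' the normal quantile infinite; when the number of trials behind a rate is
#' supplied, the rate is clamped to \eqn{[1/(2N),\ 1 - 1/(2N)]} first.
#'
#' @param hit_rate,fa_rate Proportions in \eqn{[0,1]}.
#' @param n_hit,n_fa Optional trial counts behind each rate, enabling the
#'   clamping correction.
#' @export
d_prime <- function(hit_rate, fa_rate, n_hit = NULL, n_fa = NULL) {
  clamp <- function(r, n) {
    if (is.null(n)) return(r)
    pmin(1 - 1 / (2 * n), pmax(1 / (2 * n), r))
  }
  if (any(c(hit_rate, fa_rate) < 0 | c(hit_rate, fa_rate) > 1)) {
    stop("rates must lie in [0, 1]")
  }
  stats::qnorm(clamp(hit_rate, n_hit)) - stats::qnorm(clamp(fa_rate, n_fa))
}

#' Likelihood-ratio test of a restricted MPT model
#'
#' Fits the restricted model and its unrestricted counterpart (by default
#' the same trees with all restrictions dropped, i.e. the saturated model)
#' and compares them by \eqn{\Delta G^2}, with df equal to the difference in
#' free parameters.
#'
#' @param restricted A [joint_model()] carrying the restriction under test.
#' @param counts Counts covering every condition (see [loglik_mpt()]).
#' @param unrestricted Optional comparison [joint_model()]; defaults to the
#'   saturated model on the same trees.
#' @param alpha Significance level.
#' @param n_total Trial total used for Cohen's w; defaults to the total
#'   count in the model.
#' @param ... Passed to [fit_mpt()].
#' @return Object of class `mpt_test_result`: `g_squared`, `df`, `p_value`,
#'   `effect_size_w`, `significant`, `fit_restricted`, `fit_unrestricted`.
#' @export
mpt_test <- function(restricted, counts, unrestricted = NULL, alpha = 0.05,
                     n_total = NULL, ...) {
  stopifnot(inherits(restricted, "mpt_joint"))
  if (is.null(unrestricted)) {
    unrestricted <- joint_model(restricted$trees, restrictions = list())
  }
  fit_r <- fit_mpt(restricted, counts, ...)
  fit_u <- fit_mpt(unrestricted, counts, ...)
  g2 <- max(0, fit_r$g_squared - fit_u$g_squared)
  df <- fit_r$df - fit_u$df
  if (df < 1) stop("restricted model does not reduce the free parameters")
  if (is.null(n_total)) n_total <- fit_r$n_total
  p <- chi2_p_value(g2, df)
  structure(list(
    g_squared = g2, df = df, p_value = p,
    effect_size_w = cohens_w(g2, n_total),
    n_total = n_total, alpha = alpha, significant = p < alpha,
    fit_restricted = fit_r, fit_unrestricted = fit_u
  ), class = "mpt_test_result")
}

#' @export
print.mpt_test_result <- function(x, ...) {
  cat(.format_test_line(x$g_squared, x$df, x$p_value, x$effect_size_w), "\n")
  invisible(x)
}

.format_test_line <- function(g2, df, p, w) {
  p_txt <- if (p < 0.001) "p < .001" else if (p < 0.005) "p < .01" else
    paste0("p = ", sub("^0", "", format(round(p, 2), nsmall = 2)))
  w_txt <- if (w < 0.005) "w < .01" else
    paste0("w = ", sub("^0", "", format(round(w, 2), nsmall = 2)))
  sprintf("G2(%d) = %.2f, %s, %s", df, g2, p_txt, w_txt)
}

#' Verdict on context integration from a significance pattern
#'
#' Maps the outcomes of the binary and configural context-binding tests to
#' one of the prototypical patterns: `binary_binding` if only the binary
#' test is significant, `configural_binding` if only the interaction test
#' is, `mixed` if both, `not_integrated` if neither.
#'
#' @param binary_significant,configural_significant Logical scalars.
#' @export
binding_verdict <- function(binary_significant, configural_significant) {
  stopifnot(is.logical(binary_significant), is.logical(configural_significant))
  if (binary_significant && configural_significant) return("mixed")
  if (binary_significant) return("binary_binding")
  if (configural_significant) return("configural_binding")
  "not_integrated"
}

#' Run the three-step context-binding test battery
#'
#' For every saliency level in a frequency table the battery fits, against
#' the saturated model, three restricted joint models of the baseline
#' processing trees:
#' \enumerate{
#'   \item \strong{Distractor retrieval} (one test per context relation):
#'     `prr_IR = prr_C` within the context-repeated and within the
#'     context-changed condition. A misfit shows that repeating the prime
#'     distractor retrieves the prime response (binary distractor-response
#'     binding).
#'   \item \strong{Binary context binding}: in the four-condition joint
#'     model, `prr_C` equal between context-repeated and context-changed
#'     trials. A misfit shows that repeating the context alone retrieves
#'     the prime response.
#'   \item \strong{Configural context binding} (interaction): the retrieval
#'     effect `prr_IR - prr_C` equal between context-repeated and
#'     context-changed trials, via the difference-reparameterized joint
#'     model. A misfit shows that the context modulates distractor-induced
#'     retrieval.
#' }
#' Every test has df = 1. Cohen's w uses the total trial count of the
#' tested joint model. A verdict per saliency level summarizes the binary
#' and configural outcomes (see [binding_verdict()]).
#'
#' @param table A frequency table as returned by [freq_table()] /
#'   [aggregate_and_filter()] or read with [read_frequency_table()]:
#'   counts for every `trial_type` (ignored_repetition, control) by
#'   `context_relation` (repeated, changed) cell within each saliency level.
#' @param alpha Significance level (default .05).
#' @param adjust `"none"` (raw p values drive significance) or `"holm"`
#'   (Holm-adjusted within each test family across saliency levels). Both
#'   raw and adjusted p values are always reported.
#' @param ... Passed to [fit_mpt()].
#' @return Object of class `binding_battery`: `$tests` (one row per test),
#'   `$verdicts` (named by saliency level), `$alpha`, `$adjust`,
#'   `$results` (the underlying `mpt_test_result` objects).
#' @export
run_binding_battery <- function(table, alpha = 0.05,
                                adjust = c("none", "holm"), ...) {
  adjust <- match.arg(adjust)
  table <- .validate_freq_table(table)
  sal_levels <- unique(table$saliency)
  rows <- list(); results <- list()

  for (sal in sal_levels) {
    sub <- table[table$saliency == sal, , drop = FALSE]
    cts <- list()
    for (tt in c("ignored_repetition", "control")) {
      for (cr in c("repeated", "changed")) {
        hit <- sub$trial_type == tt & sub$context_relation == cr
        if (sum(hit) != 1) {
          stop("missing or duplicated cell: trial_type=", tt,
               ", context_relation=", cr, ", saliency=", sal)
        }
        lab <- paste0(if (tt == "ignored_repetition") "IR" else "C", ":", cr)
        cts[[lab]] <- as.numeric(sub[hit, .freq_count_cols()])
      }
    }
    trees <- lapply(stats::setNames(nm = names(cts)), baseline_tree)

    add <- function(test, condition, model, labels) {
      res <- mpt_test(model, cts[labels], alpha = alpha, ...)
      key <- paste(sal, test, condition, sep = "|")
      results[[key]] <<- res
      rows[[key]] <<- data.frame(
        saliency = sal, test = test, condition = condition,
        g_squared = res$g_squared, df = res$df, p_value = res$p_value,
        effect_size_w = res$effect_size_w, n_total = res$n_total,
        stringsAsFactors = FALSE
      )
    }

    for (cr in c("repeated", "changed")) {
      labs <- paste0(c("IR:", "C:"), cr)
      add("distractor_retrieval", cr,
          joint_model(trees[labs],
                      restrict_equal(paste0("prr@IR:", cr),
                                     paste0("prr@C:", cr))),
          labs)
    }
    all4 <- names(cts)
    add("binary_context_binding", "repeated_vs_changed",
        joint_model(trees[all4],
                    restrict_equal("prr@C:repeated", "prr@C:changed")),
        all4)
    add("configural_context_binding", "repeated_vs_changed",
        joint_model(trees[all4],
                    restrict_difference(c("prr@IR:repeated", "prr@C:repeated"),
                                        c("prr@IR:changed", "prr@C:changed"))),
        all4)
  }

  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests$p_holm <- NA_real_
  for (fam in unique(tests$test)) {
    idx <- tests$test == fam
    tests$p_holm[idx] <- holm_adjust(tests$p_value[idx])
  }
  p_used <- if (adjust == "holm") tests$p_holm else tests$p_value
  tests$significant <- p_used < alpha

  verdicts <- vapply(sal_levels, function(sal) {
    bin <- tests$significant[tests$saliency == sal &
                               tests$test == "binary_context_binding"]
    conf <- tests$significant[tests$saliency == sal &
                                tests$test == "configural_context_binding"]
    binding_verdict(any(bin), any(conf))
  }, character(1))

  structure(list(tests = tests, verdicts = verdicts, alpha = alpha,
                 adjust = adjust, results = results),
            class = "binding_battery")
}

#' @export
print.binding_battery <- function(x, ...) {
  cat("Context-binding test battery (alpha =", x$alpha,
      if (x$adjust == "holm") ", Holm-adjusted)\n" else ", raw p)\n")
  for (sal in names(x$verdicts)) {
    cat("\nSaliency:", sal, " -> verdict:", x$verdicts[[sal]], "\n")
    sub <- x$tests[x$tests$saliency == sal, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-28s %-20s %s%s\n", sub$test[i], sub$condition[i],
                  .format_test_line(sub$g_squared[i], sub$df[i],
                                    sub$p_value[i], sub$effect_size_w[i]),
                  if (sub$significant[i]) "  *" else ""))
    }
  }
  invisible(x)
}
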