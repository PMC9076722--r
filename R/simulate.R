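#' Condition-specific generating parameters for a simulated experiment
#'
#' Builds the per-cell `(ci, psc, prr)` table that drives
#' [simulate_experiment()]: one row per trial type (ignored_repetition,
#' control) by context relation by saliency level. Three ready-made
#' patterns mirror the prototypical context-integration outcomes:
#' \describe{
#'   \item{`none`}{the retrieval effect `prr_IR - prr_C` and `prr_C` itself
#'     are identical in all cells (context not integrated).}
#'   \item{`configural`}{`prr_C` equal across context relations, but the
#'     retrieval effect is larger when the context repeats
#'     (`effect_repeated` vs. `effect_changed`).}
#'   \item{`binary`}{`prr_C` is elevated when the context repeats
#'     (`binary_shift`), with the same retrieval effect in both context
#'     relations.}
#' }
#' Default magnitudes: `ci = .90` (overall probe error rate ~.10, matching
#' typical performance in these tasks), `psc = .40`, `prr_c = .12`, a
#' baseline retrieval effect of `.06`, configural effects `.10` (repeated)
#' vs. `.02` (changed), and a binary shift of `.08`.
#'
#' @param spec An [design_spec()] (supplies the saliency levels).
#' @param pattern Which prototypical pattern the parameters realize.
#' @param saliency_levels Saliency levels to which the pattern applies
#'   (default: all); remaining levels get the `none` pattern.
#' @param ci,psc,prr_c Baseline branch probabilities.
#' @param effect Baseline retrieval effect `prr_IR - prr_C`.
#' @param effect_repeated,effect_changed Configural-pattern effects.
#' @param binary_shift Elevation of `prr_C` under a repeated context in the
#'   binary pattern.
#' @return Data.frame of class `mpt_sim_params` with one row per cell.
#' @export
sim_params <- function(spec, pattern = c("none", "configural", "binary"),
                       saliency_levels = NULL,
                       ci = 0.90, psc = 0.40, prr_c = 0.12, effect = 0.06,
                       effect_repeated = 0.10, effect_changed = 0.02,
                       binary_shift = 0.08) {
  stopifnot(inherits(spec, "mpt_design_spec"))
  pattern <- match.arg(pattern)
  sal_all <- names(spec$saliency)
  if (is.null(saliency_levels)) saliency_levels <- sal_all
  if (!all(saliency_levels %in% sal_all)) stop("unknown saliency level")
  grid <- expand.grid(trial_type = c("ignored_repetition", "control"),
                      context_relation = c("repeated", "changed"),
                      saliency = sal_all,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$ci <- ci; grid$psc <- psc
  base_c <- prr_c
  prr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    active <- grid$saliency[i] %in% saliency_levels && pattern != "none"
    rep_ctx <- grid$context_relation[i] == "repeated"
    pc <- base_c
    eff <- effect
    if (active && pattern == "configural") {
      eff <- if (rep_ctx) effect_repeated else effect_changed
    }
    if (active && pattern == "binary" && rep_ctx) pc <- base_c + binary_shift
    prr[i] <- if (grid$trial_type[i] == "ignored_repetition") pc + eff else pc
  }
  grid$prr <- prr
  .validate_sim_params(grid)
  class(grid) <- c("mpt_sim_params", "data.frame")
  grid
}

.validate_sim_params <- function(p) {
  need <- c("trial_type", "context_relation", "saliency", "ci", "psc", "prr")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("sim params lack column(s): ",
                         paste(miss, collapse = ", "))
  probs <- unlist(p[c("ci", "psc", "prr")])
  if (anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("all generating probabilities must lie in [0, 1]")
  }
  invisible(p)
}

#' Simulate probe responses for a realized design
#'
#' For every participant and trial, a response category is drawn from the
#' branch probabilities of the trial's cell — `(ci, (1-ci)psc,
#' (1-ci)(1-psc)prr, (1-ci)(1-psc)(1-prr))` — and mapped back to a concrete
#' response stimulus (the inverse of [classify_probe_response()]).
#' Attended-repetition trials and their controls are simulated with the
#' matching control cell's parameters and marked `analyzed = FALSE`; the
#' categorical model concerns probe responses of ignored-repetition and
#' control trials only, and prime responses are assumed correct.
#'
#' @param design A trial list from [build_design()].
#' @param params Cell parameters from [sim_params()] (or any data.frame
#'   with the same columns).
#' @param n_participants Number of simulated participants (all see the same
#'   trial list, as in the within-subjects designs emulated here).
#' @param seed Integer seed; the run is reproducible and the caller's RNG
#'   state is untouched.
#' @param ci_jitter_sd Standard deviation of a per-participant logit-normal
#'   perturbation of `ci`, emulating stable individual differences in
#'   accuracy (0 = homogeneous participants).
#' @return Data.frame of per-trial records: `participant`, `trial`,
#'   `trial_type`, `context_relation`, `saliency`, `response`, `category`
#'   (`NA` for non-analyzed filler trials), `analyzed`. The seed is kept in
#'   `attr(, "seed")`.
#' @export
simulate_experiment <- function(design, params, n_participants = 1L,
                                seed = 1L, ci_jitter_sd = 0) {
  stopifnot(is.data.frame(design), n_participants >= 1)
  .validate_sim_params(params)
  s <- attr(design, "stimuli")
  if (is.null(s)) stop("design lacks its stimulus attribute; ",
                       "use build_design()")

  # map each trial to its parameter cell (fillers borrow the control cell)
  tt_for_params <- c(ignored_repetition = "ignored_repetition",
                     control_ir = "control",
                     attended_repetition = "control",
                     control_ar = "control")[design$trial_type]
  key_t <- paste(tt_for_params, design$context_relation, design$saliency)
  key_p <- paste(params$trial_type, params$context_relation, params$saliency)
  row <- match(key_t, key_p)
  if (anyNA(row)) {
    stop("no generating parameters for cell(s): ",
         paste(unique(key_t[is.na(row)]), collapse = "; "))
  }
  ci <- params$ci[row]; psc <- params$psc[row]; prr <- params$prr[row]
  fourth <- apply(design[, c("prime_target", "probe_target",
                             "probe_distractor")], 1L,
                  function(r) setdiff(s, r)[1])

  nT <- nrow(design); nP <- as.integer(n_participants)
  idx <- rep.int(seq_len(nT), nP)
  participant <- rep(seq_len(nP), each = nT)

  draws <- .with_seed(seed, {
    ci_long <- ci[idx]
    if (ci_jitter_sd > 0) {
      offs <- stats::rnorm(nP, 0, ci_jitter_sd)
      ci_long <- stats::plogis(stats::qlogis(ci_long) + offs[participant])
    }
    p1 <- ci_long
    p2 <- (1 - ci_long) * psc[idx]
    p3 <- (1 - ci_long) * (1 - psc[idx]) * prr[idx]
    u <- stats::runif(length(idx))
    1L + (u > p1) + (u > p1 + p2) + (u > p1 + p2 + p3)
  })

  resp_by_cat <- cbind(design$probe_target, design$probe_distractor,
                       design$prime_target, fourth)
  response <- resp_by_cat[cbind(idx, draws)]
  analyzed <- design$trial_type[idx] %in% c("ignored_repetition", "control_ir")
  category <- ifelse(analyzed,
                     c("correct", "distractor_error", "prime_response_error",
                       "other_error")[draws],
                     NA_character_)

  out <- data.frame(
    participant = participant,
    trial = design$trial[idx],
    trial_type = design$trial_type[idx],
    context_relation = design$context_relation[idx],
    saliency = design$saliency[idx],
    response = response,
    category = category,
    analyzed = analyzed,
    stringsAsFactors = FALSE
  )
  attr(out, "seed") <- seed
  out
}

#' Aggregate simulated (or observed) responses into a frequency table
#'
#' Applies the participant-exclusion rule — error rate above the threshold
#' over the analyzed ignored-repetition and control trials — and pools the
#' remaining responses into per-cell four-category counts.
#'
#' @param responses Per-trial records from [simulate_experiment()] (or any
#'   data.frame with `participant`, `trial_type`, `context_relation`,
#'   `saliency`, `category`, `analyzed`).
#' @param error_rate_threshold Participants with an error rate strictly
#'   above this over their analyzed trials are excluded (default .50).
#' @return List with `table` (an `mpt_freq_table`, see [freq_table()]),
#'   `exclusions` (per-participant error rate and exclusion flag), and
#'   `threshold`.
#' @export
aggregate_and_filter <- function(responses, error_rate_threshold = 0.50) {
  need <- c("participant", "trial_type", "context_relation", "saliency",
            "category", "analyzed")
  miss <- setdiff(need, names(responses))
  if (length(miss)) stop("responses lack column(s): ",
                         paste(miss, collapse = ", "))
  r <- responses[responses$analyzed, , drop = FALSE]
  if (!nrow(r)) stop("no analyzable ignored-repetition/control trials")

  err <- tapply(r$category != "correct", r$participant, mean)
  exclusions <- data.frame(participant = as.integer(names(err)),
                           error_rate = as.numeric(err),
                           excluded = as.numeric(err) > error_rate_threshold)
  exclusions <- exclusions[order(exclusions$participant), ]
  rownames(exclusions) <- NULL
  keep <- exclusions$participant[!exclusions$excluded]
  if (!length(keep)) {
    stop("all participants excluded at error-rate threshold ",
         error_rate_threshold)
  }
  r <- r[r$participant %in% keep, , drop = FALSE]

  tt <- ifelse(r$trial_type == "ignored_repetition",
               "ignored_repetition", "control")
  cats <- c("correct", "distractor_error", "prime_response_error",
            "other_error")
  tab <- table(cell = paste(tt, r$context_relation, r$saliency, sep = "\r"),
               category = factor(r$category, levels = cats))
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  ft <- freq_table(data.frame(
    trial_type = parts[, 1], context_relation = parts[, 2],
    saliency = parts[, 3],
    n_correct = as.integer(tab[, "correct"]),
    n_distractor_error = as.integer(tab[, "distractor_error"]),
    n_prime_response_error = as.integer(tab[, "prime_response_error"]),
    n_other_error = as.integer(tab[, "other_error"]),
    stringsAsFactors = FALSE
  ))
  list(table = ft, exclusions = exclusions,
       threshold = error_rate_threshold)
}
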