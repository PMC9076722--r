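# Shared fixtures: everything is generated in code, no stored data.

baseline_probs <- function(ci, psc, prr) {
  category_probs(baseline_tree(),
                 c(ci = ci, psc = psc, prr = prr))
}

# one random four-category count table from a random baseline tree
random_count_table <- function(n_min = 50, n_max = 500) {
  p <- baseline_probs(runif(1, 0.05, 0.95), runif(1, 0.05, 0.95),
                      runif(1, 0.05, 0.95))
  stats::rmultinom(1, sample.int(n_max - n_min, 1) + n_min, p)[, 1]
}

# four-condition battery counts (one saliency level) drawn cell-by-cell
# from given prr values; returns an mpt_freq_table
battery_table <- function(prr_ir_rep, prr_c_rep, prr_ir_chg, prr_c_chg,
                          n_per_cell, ci = 0.9, psc = 0.4,
                          saliency = "moderate") {
  cells <- data.frame(
    trial_type = c("ignored_repetition", "control",
                   "ignored_repetition", "control"),
    context_relation = c("repeated", "repeated", "changed", "changed"),
    prr = c(prr_ir_rep, prr_c_rep, prr_ir_chg, prr_c_chg),
    stringsAsFactors = FALSE
  )
  counts <- t(vapply(cells$prr, function(prr) {
    stats::rmultinom(1, n_per_cell, baseline_probs(ci, psc, prr))[, 1]
  }, numeric(4)))
  freq_table(data.frame(
    trial_type = cells$trial_type,
    context_relation = cells$context_relation,
    saliency = saliency,
    n_correct = counts[, 1], n_distractor_error = counts[, 2],
    n_prime_response_error = counts[, 3], n_other_error = counts[, 4],
    stringsAsFactors = FALSE
  ))
}

# the four-condition joint model of one saliency level, optionally restricted
joint4 <- function(restrictions = list()) {
  labs <- c("IR:repeated", "C:repeated", "IR:changed", "C:changed")
  joint_model(lapply(stats::setNames(nm = labs), baseline_tree),
              restrictions)
}

counts4 <- function(tab) {
  labs <- c("IR:repeated", "C:repeated", "IR:changed", "C:changed")
  key <- paste(ifelse(tab$trial_type == "ignored_repetition", "IR", "C"),
               tab$context_relation, sep = ":")
  out <- lapply(stats::setNames(nm = labs), function(l) {
    as.numeric(tab[key == l, c("n_correct", "n_distractor_error",
                               "n_prime_response_error", "n_other_error")])
  })
  out
}
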