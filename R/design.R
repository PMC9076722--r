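#' Specification of a negative-priming experiment design
#'
#' Describes the trial construction of the two supported four-alternative
#' auditory identification designs:
#' \describe{
#'   \item{`exp1`}{three context-saliency levels (low/moderate/high loudness
#'     of a task-irrelevant tone, identities 300 Hz vs. 700 Hz), a 48-trial
#'     basic set (12 per trial type), implemented in four prime/probe
#'     context combinations and repeated per saliency level: 576 trials,
#'     24 per ignored-repetition/control by context-relation cell within
#'     each saliency level.}
#'   \item{`exp2`}{two saliency levels realized by emotional valence
#'     (moderate: neutral vowels; high: angry/disgusted vowels), a 32-trial
#'     basic set (8 per trial type): 256 trials, 16 per cell.}
#' }
#' Each trial pairs a prime and a probe presentation. In ignored-repetition
#' trials the prime distractor equals the probe target; the parallel
#' control trial replaces the prime distractor with the fourth stimulus.
#' Attended-repetition trials (prime target = probe target) and their
#' controls are included as fillers against response-change anticipation.
#'
#' @param variant `"exp1"` or `"exp2"`.
#' @param stimuli Four stimulus labels.
#' @param trials_per_cell Trials per ignored-repetition/control by
#'   context-relation cell within a saliency level (default 24 for exp1,
#'   16 for exp2). Must be divisible by 8 so that each stimulus serves
#'   equally often as probe target within the basic set.
#' @param include_attended_repetition Keep the attended-repetition filler
#'   trials in the design (they are never analyzed).
#' @param seed Integer seed driving trial sampling and ordering.
#' @return Object of class `mpt_design_spec`.
#' @export
design_spec <- function(variant = c("exp1", "exp2"),
                        stimuli = c("frog", "piano", "drum", "bell"),
                        trials_per_cell = NULL,
                        include_attended_repetition = TRUE,
                        seed = 1L) {
  variant <- match.arg(variant)
  if (length(stimuli) != 4 || anyDuplicated(stimuli)) {
    stop("exactly four distinct stimulus labels are required")
  }
  if (is.null(trials_per_cell)) {
    trials_per_cell <- if (variant == "exp1") 24L else 16L
  }
  # per basic set and trial type: trials_per_cell / 2 (two context-repeated
  # combinations realize one cell); balance over 4 probe targets needs a
  # further factor of 4; each probe target admits 6 distinct triplets
  per_type <- trials_per_cell / 2
  if (per_type != round(per_type) || per_type %% 4 != 0 || per_type > 24) {
    stop("trials_per_cell must be a multiple of 8, at most 48")
  }
  saliency <- if (variant == "exp1") {
    list(low = c("tone_300", "tone_700"),
         moderate = c("tone_300", "tone_700"),
         high = c("tone_300", "tone_700"))
  } else {
    list(moderate = c("neutral_a", "neutral_e"),
         high = c("angry_a", "disgusted_e"))
  }
  structure(list(variant = variant, stimuli = stimuli,
                 trials_per_cell = as.integer(trials_per_cell),
                 per_type = as.integer(per_type),
                 saliency = saliency,
                 include_attended_repetition = include_attended_repetition,
                 seed = as.integer(seed)),
            class = "mpt_design_spec")
}

#' Build the realized trial list of a design
#'
#' Samples a balanced basic set of stimulus triplets (each stimulus serves
#' equally often as probe target within each trial type), implements it in
#' the four prime/probe context combinations of every saliency level,
#' assigns a random prime side (the probe target is always presented on the
#' other side), and shuffles the trial order. Deterministic given
#' `spec$seed`.
#'
#' @param spec An [design_spec()].
#' @return A data.frame of trial records (class `mpt_design`) with columns
#'   `trial`, `trial_type` (`ignored_repetition`, `control_ir`,
#'   `attended_repetition`, `control_ar`), `prime_target`,
#'   `prime_distractor`, `probe_target`, `probe_distractor`,
#'   `context_prime`, `context_probe`, `context_relation`, `saliency`,
#'   `prime_side`, `probe_side`. The stimulus set is kept in
#'   `attr(, "stimuli")`.
#' @examples
#' d <- build_design(design_spec("exp1", seed = 7))
#' nrow(d)  # 576
#' @export
build_design <- function(spec) {
  stopifnot(inherits(spec, "mpt_design_spec"))
  .with_seed(spec$seed, .build_design_impl(spec))
}

.build_design_impl <- function(spec) {
  s <- spec$stimuli
  per_group <- spec$per_type / 4L

  # ordered triplets (x, t, y): t = probe target, x and y the two other
  # roles, all distinct; 6 per probe target
  sample_triplets <- function() {
    do.call(rbind, lapply(s, function(t) {
      others <- setdiff(s, t)
      grid <- expand.grid(x = others, y = others, stringsAsFactors = FALSE)
      grid <- grid[grid$x != grid$y, ]
      grid <- grid[sample.int(nrow(grid), per_group), , drop = FALSE]
      data.frame(x = grid$x, t = t, y = grid$y, stringsAsFactors = FALSE)
    }))
  }
  fourth <- function(a, b, c) {
    vapply(seq_along(a), function(i) setdiff(s, c(a[i], b[i], c[i])),
           character(1))
  }

  # ignored repetition: prime (target x, distractor t) -> probe (target t,
  # distractor y); control: the prime distractor becomes the fourth sound
  tri_ir <- sample_triplets()
  ir <- data.frame(trial_type = "ignored_repetition",
                   prime_target = tri_ir$x, prime_distractor = tri_ir$t,
                   probe_target = tri_ir$t, probe_distractor = tri_ir$y,
                   stringsAsFactors = FALSE)
  tri_c <- sample_triplets()
  ctrl <- data.frame(trial_type = "control_ir",
                     prime_target = tri_c$x,
                     prime_distractor = fourth(tri_c$x, tri_c$t, tri_c$y),
                     probe_target = tri_c$t, probe_distractor = tri_c$y,
                     stringsAsFactors = FALSE)
  basic <- rbind(ir, ctrl)

  if (spec$include_attended_repetition) {
    # attended repetition: prime target = probe target t; control: the
    # prime target is replaced by the fourth sound
    tri_ar <- sample_triplets()
    ar <- data.frame(trial_type = "attended_repetition",
                     prime_target = tri_ar$t, prime_distractor = tri_ar$x,
                     probe_target = tri_ar$t, probe_distractor = tri_ar$y,
                     stringsAsFactors = FALSE)
    tri_ca <- sample_triplets()
    car <- data.frame(trial_type = "control_ar",
                      prime_target = fourth(tri_ca$x, tri_ca$t, tri_ca$y),
                      prime_distractor = tri_ca$x,
                      probe_target = tri_ca$t, probe_distractor = tri_ca$y,
                      stringsAsFactors = FALSE)
    basic <- rbind(basic, ar, car)
  }

  blocks <- list()
  for (sal in names(spec$saliency)) {
    ids <- spec$saliency[[sal]]
    combos <- list(c(ids[1], ids[1]), c(ids[2], ids[2]),
                   c(ids[1], ids[2]), c(ids[2], ids[1]))
    for (cmb in combos) {
      blk <- basic
      blk$context_prime <- cmb[1]
      blk$context_probe <- cmb[2]
      blk$context_relation <- if (cmb[1] == cmb[2]) "repeated" else "changed"
      blk$saliency <- sal
      blocks[[length(blocks) + 1L]] <- blk
    }
  }
  design <- do.call(rbind, blocks)
  design <- design[sample.int(nrow(design)), , drop = FALSE]
  design$prime_side <- sample(c("left", "right"), nrow(design), replace = TRUE)
  design$probe_side <- ifelse(design$prime_side == "left", "right", "left")
  design$trial <- seq_len(nrow(design))
  rownames(design) <- NULL
  design <- design[, c("trial", "trial_type", "prime_target",
                       "prime_distractor", "probe_target", "probe_distractor",
                       "context_prime", "context_probe", "context_relation",
                       "saliency", "prime_side", "probe_side")]
  attr(design, "stimuli") <- s
  attr(design, "variant") <- spec$variant
  class(design) <- c("mpt_design", "data.frame")
  design
}

#' Classify a probe response into the four model categories
#'
#' For ignored-repetition and control trials, the probe response falls into
#' exactly one of four categories: `correct` (the probe target),
#' `distractor_error` (the probe distractor), `prime_response_error`
#' (re-execution of the prime response, i.e. the prime target's key), or
#' `other_error` (the remaining response option). The three reference
#' stimuli are pairwise distinct in these trial types, so the categories
#' are mutually exclusive and exhaustive.
#'
#' @param trials One or more trial records ([build_design()] rows).
#' @param response Character vector of response stimuli (recycled scalar or
#'   one per trial).
#' @param stimuli The four stimulus labels; defaults to
#'   `attr(trials, "stimuli")`.
#' @return Character vector of categories.
#' @export
classify_probe_response <- function(trials, response,
                                    stimuli = attr(trials, "stimuli")) {
  if (!all(trials$trial_type %in% c("ignored_repetition", "control_ir",
                                    "control"))) {
    stop("probe-response classification applies to ignored-repetition ",
         "and control trials only")
  }
  if (is.null(stimuli)) {
    stimuli <- unique(c(trials$prime_target, trials$prime_distractor,
                        trials$probe_target, trials$probe_distractor))
  }
  if (length(response) == 1L) response <- rep(response, nrow(trials))
  if (length(response) != nrow(trials)) {
    stop("`response` must have one entry per trial")
  }
  if (!all(response %in% stimuli)) {
    stop("unknown response stimulus: ",
         paste(unique(setdiff(response, stimuli)), collapse = ", "))
  }
  ifelse(response == trials$probe_target, "correct",
    ifelse(response == trials$probe_distractor, "distractor_error",
      ifelse(response == trials$prime_target, "prime_response_error",
             "other_error")))
}
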