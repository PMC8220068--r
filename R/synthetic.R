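#' The twelve-class forced-choice label set
#'
#' The label set of the forced-choice labeling experiment: the full
#' fifteen-class catalog minus Following, Guarding and Playing, which
#' tended to be confused with other classes or described too broadly to
#' serve as unambiguous labels.
#'
#' @return Character vector of 12 class names.
#' @export
experiment_label_set <- function() {
  setdiff(names(interaction_catalog()),
          c("Following", "Guarding", "Playing"))
}

#' Default sum-to-zero animacy generator parameters
#'
#' Grand mean and agent effect at the magnitudes reported for such
#' stimuli (overall mean about 53 on the 0-100 scale; the circle rated
#' about 8 points below the rectangle), a symmetric spread of class
#' effects, subject-intercept SD 5 and residual SD 10.
#'
#' @param labels class labels (defines the number of class effects).
#' @return A list with `alpha0`, `beta` (length 2, sums to 0), `gamma`
#'   (sums to 0), `sigma_b`, `sigma`.
#' @export
default_animacy_params <- function(labels = experiment_label_set()) {
  nc <- length(labels)
  gamma <- seq(-(nc - 1), nc - 1, length.out = nc)
  gamma <- gamma - mean(gamma)
  names(gamma) <- labels
  list(alpha0 = 53.27,
       beta = c(circle = -8.37, rectangle = 8.37),
       gamma = gamma, sigma_b = 5, sigma = 10)
}

#' Specification for the synthetic-response generator
#'
#' Bundles everything needed to emulate the behavioural experiments:
#' a row-stochastic confusion kernel (the probability that a video of a
#' true class is reported as each label), an additive per-block
#' learning increment on the correct-label probability (off-diagonal
#' mass renormalized), the design sizes, and the animacy-model
#' generator parameters.
#'
#' @param labels class label set.
#' @param confusion_kernel row-stochastic matrix over `labels`; default
#'   0.65 on the diagonal with the remainder spread uniformly.
#' @param learning_increment additive increase of the diagonal kernel
#'   probability per block (block 1 is the baseline).
#' @param n_subjects,n_blocks,trials_per_block design sizes;
#'   `trials_per_block` must be a multiple of `length(labels)` so
#'   trials are balanced across classes within block.
#' @param labels_per_trial reported labels per trial (1-3; default 1).
#' @param animacy_params see [default_animacy_params()].
#' @param seed integer seed; every generator output is a deterministic
#'   function of the spec.
#' @return An object of class `response_generator_spec`.
#' @export
response_generator_spec <- function(labels = experiment_label_set(),
                                    confusion_kernel = NULL,
                                    learning_increment = 0.03,
                                    n_subjects = 13L, n_blocks = 5L,
                                    trials_per_block = length(labels),
                                    labels_per_trial = 1L,
                                    animacy_params =
                                      default_animacy_params(labels),
                                    seed = 1L) {
  nl <- length(labels)
  if (nl < 2L) stop("need at least 2 labels")
  if (is.null(confusion_kernel)) {
    confusion_kernel <- matrix((1 - 0.65) / (nl - 1), nl, nl,
                               dimnames = list(labels, labels))
    diag(confusion_kernel) <- 0.65
  }
  K <- as.matrix(confusion_kernel)
  if (!identical(dim(K), c(nl, nl)))
    stop("confusion_kernel must be ", nl, " x ", nl)
  dimnames(K) <- list(labels, labels)
  if (any(K < 0) || any(abs(rowSums(K) - 1) > 1e-8))
    stop("confusion_kernel rows must be probability distributions")
  if (trials_per_block %% nl != 0L)
    stop("trials_per_block must be a multiple of the number of labels")
  if (labels_per_trial < 1L || labels_per_trial > 3L)
    stop("labels_per_trial must be between 1 and 3")
  if (animacy_params$sigma_b < 0 || animacy_params$sigma < 0)
    stop("animacy standard deviations must be >= 0")
  # every learning-adjusted row must remain a valid distribution
  for (b in seq_len(n_blocks)) .adjust_kernel(K, learning_increment, b)
  structure(list(labels = labels, confusion_kernel = K,
                 learning_increment = learning_increment,
                 n_subjects = as.integer(n_subjects),
                 n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 labels_per_trial = as.integer(labels_per_trial),
                 animacy_params = animacy_params,
                 seed = as.integer(seed)),
            class = "response_generator_spec")
}

# Bump each diagonal entry by increment * (block - 1), clamp to [0, 1]
# and rescale the off-diagonal mass so rows stay distributions.
.adjust_kernel <- function(K, increment, block) {
  out <- K
  for (i in seq_len(nrow(K))) {
    p0 <- K[i, i]
    p1 <- min(1, max(0, p0 + increment * (block - 1)))
    if (p0 < 1) {
      out[i, ] <- K[i, ] * (1 - p1) / (1 - p0)
    } else {
      out[i, ] <- 0
    }
    out[i, i] <- p1
  }
  if (any(out < 0) || any(abs(rowSums(out) - 1) > 1e-8))
    stop("learning adjustment at block ", block,
         " does not leave valid probability rows")
  out
}

#' Generate a synthetic label-response table
#'
#' Emulates the forced-choice labeling task: per subject and block,
#' every class is presented equally often in a seeded pseudo-random
#' order, and the reported label(s) are drawn from the
#' (learning-adjusted) kernel row of the true class — multiple labels,
#' when requested, are drawn without replacement.
#'
#' @param spec a [response_generator_spec()].
#' @return A label-response table (data.frame with columns `subject`,
#'   `block`, `true_class`, `reported`) passing
#'   [validate_label_responses()].
#' @export
generate_label_responses <- function(spec) {
  if (!inherits(spec, "response_generator_spec"))
    stop("spec must be a response_generator_spec")
  set.seed(spec$seed)
  labels <- spec$labels
  reps <- spec$trials_per_block / length(labels)
  rows <- vector("list", spec$n_subjects * spec$n_blocks)
  k <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (b in seq_len(spec$n_blocks)) {
      K <- .adjust_kernel(spec$confusion_kernel,
                          spec$learning_increment, b)
      truth <- sample(rep(labels, reps))
      reported <- vapply(truth, function(cl) {
        picked <- sample(labels, spec$labels_per_trial,
                         replace = FALSE, prob = K[cl, ])
        paste(picked, collapse = ";")
      }, character(1))
      k <- k + 1L
      rows[[k]] <- data.frame(subject = s, block = b,
                              true_class = truth, reported = reported,
                              row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_label_responses(out)
  out
}

#' Generate a synthetic animacy-rating table
#'
#' Draws ratings from the mixed-effects animacy model used for
#' analysis: grand mean plus sum-to-zero agent and class effects plus a
#' per-subject random intercept `N(0, sigma_b^2)` and residual noise
#' `N(0, sigma^2)`, truncated to the 0-100 rating scale.
#'
#' @param spec a [response_generator_spec()].
#' @return An animacy-rating table (columns `subject`, `agent`,
#'   `class`, `rating`) passing [validate_animacy_ratings()].
#' @export
generate_animacy_ratings <- function(spec) {
  if (!inherits(spec, "response_generator_spec"))
    stop("spec must be a response_generator_spec")
  ap <- spec$animacy_params
  if (ap$sigma_b < 0 || ap$sigma < 0)
    stop("animacy standard deviations must be >= 0")
  set.seed(derive_seed(spec$seed, 101L))
  agents <- names(ap$beta)
  classes <- spec$labels
  b0 <- stats::rnorm(spec$n_subjects, 0, ap$sigma_b)
  grid <- expand.grid(subject = seq_len(spec$n_subjects),
                      agent = agents, class = classes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ap$alpha0 + ap$beta[grid$agent] +
    ap$gamma[match(grid$class, classes)] + b0[grid$subject]
  rating <- mu + stats::rnorm(nrow(grid), 0, ap$sigma)
  grid$rating <- pmin(100, pmax(0, unname(rating)))
  validate_animacy_ratings(grid)
  grid
}

#' Generate synthetic per-subject similarity ratings
#'
#' Emulates the semantic survey: each subject's similarity matrix is
#' the true similarity `10 * (1 - D)` plus symmetric Gaussian rater
#' noise, clamped to the 0-10 scale; self-similarity is fixed at 10.
#'
#' @param true_D true semantic distance matrix in `[0, 1]` (symmetric,
#'   zero diagonal).
#' @param rater_noise_sd rater noise SD in rating units.
#' @param n_subjects number of simulated raters.
#' @param seed integer seed.
#' @return A list of `n_subjects` symmetric similarity matrices on the
#'   0-10 scale.
#' @export
generate_similarity_ratings <- function(true_D, rater_noise_sd = 1,
                                        n_subjects = 16L, seed = 1L) {
  D <- .check_distance_matrix(true_D)
  if (rater_noise_sd < 0) stop("rater_noise_sd must be >= 0")
  set.seed(seed)
  n <- nrow(D)
  s_true <- 10 * (1 - D)
  lapply(seq_len(n_subjects), function(i) {
    E <- matrix(0, n, n)
    up <- upper.tri(E)
    E[up] <- stats::rnorm(sum(up), 0, rater_noise_sd)
    E <- E + t(E)
    s <- s_true + E
    s[] <- pmin(10, pmax(0, s))
    diag(s) <- 10
    dimnames(s) <- dimnames(true_D)
    s
  })
}

#' Deterministic block-structured semantic distance matrix
#'
#' A synthetic stand-in for an empirically measured class-distance
#' matrix: labels are assigned round-robin to `n_clusters` groups,
#' within-group pairs get a small distance and between-group pairs a
#' large one. Useful as the ground truth for similarity-survey
#' simulations and embedding tests.
#'
#' @param labels class labels.
#' @param n_clusters number of semantic groups.
#' @param within,between within- and between-group distances in
#'   `[0, 1]`, `within < between`.
#' @return A symmetric `semantic_distance` matrix.
#' @export
synthetic_semantic_distance <- function(labels = experiment_label_set(),
                                        n_clusters = 4L, within = 0.25,
                                        between = 0.75) {
  if (within >= between) stop("within must be < between")
  n <- length(labels)
  grp <- rep(seq_len(n_clusters), length.out = n)
  D <- matrix(between, n, n, dimnames = list(labels, labels))
  D[outer(grp, grp, `==`)] <- within
  diag(D) <- 0
  structure(D, class = c("semantic_distance", "matrix"))
}
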