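#' Validate an animacy-rating table
#'
#' Rows are (subject, agent, class, rating) with ratings on the 0-100
#' scale (a 0-10 Likert scale rescaled by 10).
#'
#' @param ratings data.frame with columns `subject`, `agent`, `class`,
#'   `rating`.
#' @return `ratings`, invisibly; stops on violation.
#' @export
validate_animacy_ratings <- function(ratings) {
  need <- c("subject", "agent", "class", "rating")
  missing <- setdiff(need, names(ratings))
  if (length(missing))
    stop("rating table is missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(!is.finite(ratings$rating)) ||
      any(ratings$rating < 0 | ratings$rating > 100))
    stop("ratings must lie in [0, 100]")
  invisible(ratings)
}

#' Fit the mixed-effects animacy model
#'
#' Linear mixed model of animacy ratings with Agent and Social
#' Interaction as sum-to-zero fixed effects and Subject as a random
#' intercept:
#' \deqn{Animacy_{sl} = \alpha_0 + \sum_i \beta_i Agent(i,l) +
#'   \sum_i \gamma_i Class(i,l) + b_{0s} + \epsilon_{sl}}
#' with \eqn{\sum\beta_i = 0}, \eqn{\sum\gamma_i = 0},
#' \eqn{b_{0s} \sim N(0, \sigma_b^2)},
#' \eqn{\epsilon \sim N(0, \sigma^2)}. Under the constraint,
#' \eqn{\alpha_0} is the overall mean rating. Estimated by REML via
#' \pkg{lme4}. Inference uses residual degrees of freedom
#' `N - p` with `p = 1 + (N_a - 1) + (N_c - 1)` (e.g. 13 subjects x 2
#' agents x 12 classes gives `312 - 13 = 299`).
#'
#' @param ratings a table accepted by [validate_animacy_ratings()];
#'   every agent x class cell must be observed and at least two
#'   subjects are required.
#' @return An object of class `animacy_fit`: list with `alpha0`, `beta`
#'   (named, sums to zero), `gamma` (named, sums to zero), `sigma_b2`,
#'   `sigma2`, `df_residual`, `tests` (per-effect estimates, SEs, t and
#'   p), `class_F` (overall class-effect F test), and the underlying
#'   `lme4` fit as `model`.
#' @export
fit_animacy_model <- function(ratings) {
  validate_animacy_ratings(ratings)
  d <- data.frame(subject = factor(ratings$subject),
                  agent = factor(ratings$agent),
                  class = factor(ratings$class),
                  rating = as.numeric(ratings$rating))
  if (nlevels(d$subject) < 2L) stop("need at least 2 subjects")
  cells <- table(d$agent, d$class)
  if (any(cells == 0L)) {
    idx <- which(cells == 0L, arr.ind = TRUE)
    stop("design error, missing agent x class cell(s): ",
         paste(rownames(cells)[idx[, 1]], colnames(cells)[idx[, 2]],
               sep = ":", collapse = ", "))
  }
  contrasts(d$agent) <- stats::contr.sum(nlevels(d$agent))
  contrasts(d$class) <- stats::contr.sum(nlevels(d$class))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(rating ~ agent + class + (1 | subject), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))

  fe <- lme4::fixef(fit)
  na <- nlevels(d$agent); nc <- nlevels(d$class)
  agent_idx <- 1L + seq_len(na - 1L)
  class_idx <- na + seq_len(nc - 1L)
  expand <- function(coefs, levels) {
    stats::setNames(c(coefs, -sum(coefs)), levels)
  }
  beta <- expand(fe[agent_idx], levels(d$agent))
  gamma <- expand(fe[class_idx], levels(d$class))

  N <- nrow(d)
  p <- 1L + (na - 1L) + (nc - 1L)
  df_res <- N - p
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  tval <- fe / se
  tests <- data.frame(term = names(fe), estimate = unname(fe),
                      se = unname(se), t = unname(tval),
                      df = df_res,
                      p = 2 * stats::pt(abs(unname(tval)), df_res,
                                        lower.tail = FALSE))

  # Wald F for the joint class effect (all gamma equal zero)
  cf <- fe[class_idx]
  Vc <- V[class_idx, class_idx, drop = FALSE]
  Fstat <- tryCatch(
    as.numeric(t(cf) %*% solve(Vc, cf)) / (nc - 1L),
    error = function(e) NA_real_)
  class_F <- list(F = Fstat, df1 = nc - 1L, df2 = df_res,
                  p = stats::pf(Fstat, nc - 1L, df_res, lower.tail = FALSE))

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_b2 <- vc$vcov[vc$grp == "subject"]
  structure(list(alpha0 = unname(fe[1]), beta = beta, gamma = gamma,
                 sigma_b2 = sigma_b2, sigma2 = stats::sigma(fit)^2,
                 df_residual = df_res, tests = tests, class_F = class_F,
                 n_agents = na, n_classes = nc,
                 class_levels = levels(d$class),
                 class_vcov = V[class_idx, class_idx, drop = FALSE],
                 model = fit),
            class = "animacy_fit")
}

#' @export
print.animacy_fit <- function(x, ...) {
  cat("Animacy mixed-model fit\n",
      "  alpha0 (grand mean): ", format(x$alpha0, digits = 4), "\n",
      "  sigma_b^2: ", format(x$sigma_b2, digits = 4),
      "  sigma^2: ", format(x$sigma2, digits = 4), "\n",
      "  residual df: ", x$df_residual, "\n",
      "  class effect: F(", x$class_F$df1, ",", x$class_F$df2, ") = ",
      format(x$class_F$F, digits = 4), ", p = ",
      format(x$class_F$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Post-hoc pairwise class contrasts of the animacy model
#'
#' For every unordered pair of interaction classes, a 1-df Wald F test
#' of \eqn{\gamma_i = \gamma_j}, with Bonferroni adjustment (p-values
#' multiplied by the number of pairs and capped at 1). Denominator
#' degrees of freedom are the fit's residual df.
#'
#' @param fit an [fit_animacy_model()] result.
#' @return A data.frame with columns `class_i`, `class_j`, `F`, `df1`,
#'   `df2`, `p`, `p_adj`.
#' @export
posthoc_class_contrasts <- function(fit) {
  if (!inherits(fit, "animacy_fit")) stop("fit must be an animacy_fit")
  lv <- fit$class_levels
  nc <- length(lv)
  # gamma = C %*% theta for the nc-1 sum-contrast coefficients theta
  C <- rbind(diag(nc - 1L), -1)
  theta <- fit$gamma[seq_len(nc - 1L)]  # equals the raw coefficients
  V <- fit$class_vcov
  pairs <- utils::combn(nc, 2)
  n_pairs <- ncol(pairs)
  res <- apply(pairs, 2, function(ij) {
    l <- C[ij[1], ] - C[ij[2], ]
    est <- sum(l * theta)
    v <- as.numeric(t(l) %*% V %*% l)
    Fstat <- est^2 / v
    p <- stats::pf(Fstat, 1, fit$df_residual, lower.tail = FALSE)
    c(Fstat, p)
  })
  data.frame(class_i = lv[pairs[1, ]], class_j = lv[pairs[2, ]],
             F = res[1, ], df1 = 1L, df2 = fit$df_residual,
             p = res[2, ], p_adj = pmin(1, res[2, ] * n_pairs))
}
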