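# Bayesian assessment of multimodality for a fixation's angular-offset
# distribution: a univariate Gaussian mixture with an unknown number of
# components (1..kmax) is sampled by reversible-jump MCMC in the
# Richardson-Green formulation (split/merge and birth/death moves over k,
# conjugate Gibbs updates within k). The posterior over k yields the Bayes
# factor for "more than one component" against the prior odds.

#' Prior specification for the mixture fit
#'
#' Richardson-Green data-dependent defaults: component means normal over the
#' data range, precisions Gamma with a hyperprior on the rate, weights
#' symmetric Dirichlet(1), k uniform on 1..kmax.
#'
#' @param kmax Maximum number of components (default 5).
#' @param k_prior Prior probabilities over k = 1..kmax (default uniform).
#' @param delta Dirichlet concentration for the weights (default 1).
#' @param alpha Shape of the Gamma prior on component precisions (default 2).
#' @param g,h_scale Hyperprior on the precision rate beta ~ Gamma(g, h) with
#'   h = h_scale / R^2 where R is the data range (defaults 0.2 and 10).
#' @return A \code{prior_spec} list.
#' @export
prior_spec <- function(kmax = 5, k_prior = rep(1 / kmax, kmax), delta = 1,
                       alpha = 2, g = 0.2, h_scale = 10) {
  stopifnot(kmax >= 1, length(k_prior) == kmax, all(k_prior >= 0),
            abs(sum(k_prior) - 1) < 1e-9, delta > 0, alpha > 0, g > 0,
            h_scale > 0)
  structure(list(kmax = kmax, k_prior = k_prior, delta = delta,
                 alpha = alpha, g = g, h_scale = h_scale),
            class = "prior_spec")
}

#' Prior odds of more than one component
#'
#' @param prior A \code{\link{prior_spec}}.
#' @param method \code{"analytic"} (ratio of prior masses) or
#'   \code{"simulation"} (empirical odds from prior draws of k).
#' @param n_sim Draws for the simulation method.
#' @param seed Seed for the simulation method.
#' @return The prior odds a = P(k > 1) / P(k = 1).
#' @export
prior_odds_multimodal <- function(prior, method = c("analytic", "simulation"),
                                  n_sim = 1e5, seed = 1) {
  method <- match.arg(method)
  if (prior$k_prior[1] <= 0) stop("prior mass on k = 1 is zero")
  if (method == "analytic") {
    return((1 - prior$k_prior[1]) / prior$k_prior[1])
  }
  ks <- with_seed(seed,
                  sample.int(prior$kmax, n_sim, TRUE, prob = prior$k_prior))
  p1 <- mean(ks == 1)
  if (p1 == 0) stop("no prior draws of k = 1; increase n_sim")
  (1 - p1) / p1
}

#' Log Bayes factor for multimodality
#'
#' b = P(k > 1) / P(k = 1) from the posterior over k; BF = b / a with a the
#' prior odds; the natural log is returned. If P(k > 1) = 0 the sentinel
#' log(0.003) is returned; if P(k = 1) = 0, +Inf (replaced at report time by
#' the highest finite value in the batch, see
#' \code{\link{histogram_report}}).
#'
#' @param post_k Posterior probabilities over k = 1..kmax.
#' @param prior A \code{\link{prior_spec}} (or a single number, the prior
#'   odds a).
#' @return log Bayes factor (natural log), possibly \code{Inf} or the
#'   log(0.003) sentinel.
#' @export
bayes_factor <- function(post_k, prior) {
  if (any(post_k < 0) || abs(sum(post_k) - 1) > 1e-6) {
    stop("post_k must be a probability vector")
  }
  p1 <- post_k[1]
  pm <- 1 - p1
  if (pm <= 0) return(log(0.003))
  if (p1 <= 0) return(Inf)
  a <- if (inherits(prior, "prior_spec")) prior_odds_multimodal(prior) else
    as.numeric(prior)
  if (a <= 0) stop("prior odds must be positive")
  log((pm / p1) / a)
}

#' Classify Bayes-factor evidence for multimodality
#'
#' log(BF) <= 1: unimodal (no evidence); (1, 3]: positive; (3, 5]: strong;
#' > 5: very strong.
#'
#' @param log_bf Log Bayes factor(s); sentinels allowed.
#' @return Factor with levels \code{unimodal, positive, strong, very_strong}.
#' @export
classify_evidence <- function(log_bf) {
  cut(log_bf, breaks = c(-Inf, 1, 3, 5, Inf),
      labels = c("unimodal", "positive", "strong", "very_strong"),
      right = TRUE)
}

#' Component with the maximum weight
#'
#' @param fit A point-estimate mixture: list with \code{means}, \code{sds},
#'   \code{weights}. Weight ties go to the component with the smaller mean.
#' @return List with \code{mean}, \code{sd}, \code{weight}.
#' @export
max_weight_component <- function(fit) {
  o <- order(-fit$weights, fit$means)
  i <- o[1]
  list(mean = fit$means[i], sd = fit$sds[i], weight = fit$weights[i])
}

#' Fit a Gaussian mixture with unknown k by reversible-jump MCMC
#'
#' One sweep per iteration: Gibbs updates of weights, means (order-preserving
#' Metropolis), variances, the precision-rate hyperparameter and the
#' allocations, followed by a split/merge move (probability 1/2) or a
#' birth/death move for empty components.
#'
#' @param offsets Angular offsets, degrees; NaNs are dropped.
#' @param prior A \code{\link{prior_spec}}.
#' @param n_iter Retained iterations (default 2000).
#' @param burn_in Discarded iterations (default 500).
#' @param seed Integer seed.
#' @param likelihood If \code{FALSE}, the data contribution is switched off
#'   everywhere (a prior-recovery diagnostic: the chain then samples the
#'   prior over k and BF = 1 up to Monte-Carlo error).
#' @param min_n Minimum usable sample size (default 50).
#' @return A \code{mixture_posterior}: list with \code{k_draws} (length
#'   \code{n_iter}), \code{post_k}, \code{point_fit} (means/sds/weights
#'   conditional on the modal k, components sorted by mean), \code{log_bf},
#'   \code{evidence}, \code{prior_odds}, \code{n}.
#' @export
fit_rjmcmc <- function(offsets, prior = prior_spec(), n_iter = 2000,
                       burn_in = 500, seed = 1, likelihood = TRUE,
                       min_n = 50) {
  y <- offsets[!is.na(offsets)]
  n <- length(y)
  if (n < min_n) stop("need at least ", min_n, " non-NaN offsets")
  if (stats::var(y) == 0) stop("degenerate input: zero variance")
  kmax <- prior$kmax
  R <- diff(range(y)); xi <- mean(range(y))
  kappa <- 1 / R^2
  alpha <- prior$alpha; delta <- prior$delta
  g <- prior$g; h <- prior$h_scale / R^2
  lik <- likelihood

  with_seed(seed, {
    # initial state: k = 1
    k <- 1L
    mu <- if (lik) mean(y) else stats::rnorm(1, xi, 1 / sqrt(kappa))
    s2 <- if (lik) stats::var(y) else
      1 / stats::rgamma(1, alpha, rate = stats::rgamma(1, g, rate = h))
    w <- 1
    z <- rep(1L, n)
    beta <- stats::rgamma(1, g, rate = h)

    total <- n_iter + burn_in
    k_draws <- integer(n_iter)
    draws <- vector("list", n_iter)

    log_phi <- function(yy, m, v) {
      if (!lik) return(rep(0, length(yy)))
      stats::dnorm(yy, m, sqrt(v), log = TRUE)
    }

    for (it in seq_len(total)) {
      nj <- tabulate(z, k)

      # weights | z
      w <- as.numeric(stats::rgamma(k, delta + nj, 1))
      w <- w / sum(w)

      # means | ... (order-preserving: reject proposals breaking the order)
      for (j in seq_len(k)) {
        if (lik) {
          sy <- sum(y[z == j])
          prec <- kappa + nj[j] / s2[j]
          m_new <- stats::rnorm(1, (kappa * xi + sy / s2[j]) / prec,
                                1 / sqrt(prec))
        } else {
          m_new <- stats::rnorm(1, xi, 1 / sqrt(kappa))
        }
        lo <- if (j > 1) mu[j - 1] else -Inf
        hi <- if (j < k) mu[j + 1] else Inf
        if (m_new > lo && m_new < hi) mu[j] <- m_new
      }

      # variances | ...
      for (j in seq_len(k)) {
        ss <- if (lik) sum((y[z == j] - mu[j])^2) else 0
        nn <- if (lik) nj[j] else 0
        s2[j] <- 1 / stats::rgamma(1, alpha + nn / 2, rate = beta + ss / 2)
      }

      # hyperparameter beta
      beta <- stats::rgamma(1, g + k * alpha, rate = h + sum(1 / s2))

      # allocations | ...
      if (k == 1) {
        z <- rep(1L, n)
      } else {
        lp <- vapply(seq_len(k),
                     function(j) log(w[j]) + log_phi(y, mu[j], s2[j]),
                     numeric(n))
        lp <- lp - apply(lp, 1, max)
        p <- exp(lp)
        cp <- p / rowSums(p)
        u <- stats::runif(n)
        z <- rowSums(u > t(apply(cp, 1, cumsum))) + 1L
        z <- as.integer(pmin(z, k))
      }
      nj <- tabulate(z, k)

      # trans-dimensional move
      if (stats::runif(1) < 0.5) {
        res <- move_split_merge(y, k, w, mu, s2, z, nj, kmax, delta, alpha,
                                beta, kappa, xi, lik)
      } else {
        res <- move_birth_death(n, k, w, mu, s2, z, nj, kmax, alpha, beta,
                                kappa, xi)
      }
      k <- res$k; w <- res$w; mu <- res$mu; s2 <- res$s2; z <- res$z

      if (it > burn_in) {
        k_draws[it - burn_in] <- k
        draws[[it - burn_in]] <- list(w = w, mu = mu, s2 = s2)
      }
    }

    post_k <- tabulate(k_draws, kmax) / n_iter
    a <- prior_odds_multimodal(prior)
    lbf <- bayes_factor(post_k, a)

    k_modal <- which.max(post_k)
    sel <- which(k_draws == k_modal)
    avg <- function(get) {
      m <- vapply(draws[sel], get, numeric(k_modal))
      if (k_modal == 1) mean(m) else rowMeans(m)
    }
    pf <- list(means = avg(function(d) d$mu),
               sds = avg(function(d) sqrt(d$s2)),
               weights = avg(function(d) d$w))
    pf$weights <- pf$weights / sum(pf$weights)

    structure(list(k_draws = k_draws, post_k = post_k, point_fit = pf,
                   log_bf = lbf, evidence = classify_evidence(lbf),
                   prior_odds = a, n = n, k_modal = k_modal,
                   draws = draws),
              class = "mixture_posterior")
  })
}

#' @export
print.mixture_posterior <- function(x, ...) {
  cat(sprintf("<mixture_posterior> n=%d, modal k=%d, log(BF)=%.3f [%s]\n",
              x$n, x$k_modal, x$log_bf, as.character(x$evidence)))
  cat("P(k):", paste(sprintf("%.3f", x$post_k), collapse = " "), "\n")
  invisible(x)
}

# split/merge move (Richardson-Green). Returns the new state.
move_split_merge <- function(y, k, w, mu, s2, z, nj, kmax, delta, alpha,
                             beta, kappa, xi, lik) {
  keep <- list(k = k, w = w, mu = mu, s2 = s2, z = z)
  b_k <- if (k < kmax) 0.5 else 0
  d_k <- if (k > 1) 0.5 else 0
  u0 <- stats::runif(1)
  lphi <- function(yy, m, v) {
    if (!lik) return(rep(0, length(yy)))
    stats::dnorm(yy, m, sqrt(v), log = TRUE)
  }

  if (u0 < b_k) {
    # ---- split ----
    j <- sample.int(k, 1)
    u1 <- stats::rbeta(1, 2, 2); u2 <- stats::rbeta(1, 2, 2)
    u3 <- stats::rbeta(1, 1, 1)
    ws <- w[j]; ms <- mu[j]; vs <- s2[j]
    w1 <- ws * u1; w2 <- ws * (1 - u1)
    m1 <- ms - u2 * sqrt(vs) * sqrt(w2 / w1)
    m2 <- ms + u2 * sqrt(vs) * sqrt(w1 / w2)
    v1 <- u3 * (1 - u2^2) * vs * ws / w1
    v2 <- (1 - u3) * (1 - u2^2) * vs * ws / w2
    # adjacency: no other mean may lie between the two new means
    others <- mu[-j]
    if (any(others > m1 & others < m2)) return(keep)

    idx <- which(z == j)
    l1 <- 0L; la <- 0
    assign1 <- logical(length(idx))
    if (length(idx)) {
      p1 <- w1 * exp(lphi(y[idx], m1, v1))
      p2 <- w2 * exp(lphi(y[idx], m2, v2))
      pr <- p1 / (p1 + p2)
      pr[is.na(pr)] <- 0.5
      assign1 <- stats::runif(length(idx)) < pr
      l1 <- sum(assign1)
      la <- sum(log(ifelse(assign1, pr, 1 - pr)))
    }
    l2 <- length(idx) - l1

    loglik <- sum(lphi(y[idx][assign1], m1, v1)) +
      sum(lphi(y[idx][!assign1], m2, v2)) - sum(lphi(y[idx], ms, vs))

    log_prior <- log(k + 1) +
      (delta - 1 + l1) * log(w1) + (delta - 1 + l2) * log(w2) -
      (delta - 1 + l1 + l2) * log(ws) - lbeta(delta, k * delta) +
      0.5 * log(kappa / (2 * pi)) -
      0.5 * kappa * ((m1 - xi)^2 + (m2 - xi)^2 - (ms - xi)^2) +
      alpha * log(beta) - lgamma(alpha) +
      (-alpha - 1) * (log(v1) + log(v2) - log(vs)) -
      beta * (1 / v1 + 1 / v2 - 1 / vs)

    d_next <- 0.5  # death prob at k+1 (k+1 >= 2)
    log_prop <- log(d_next / b_k) - la -
      stats::dbeta(u1, 2, 2, log = TRUE) -
      stats::dbeta(u2, 2, 2, log = TRUE) -
      stats::dbeta(u3, 1, 1, log = TRUE)
    log_jac <- log(ws) + log(abs(m1 - m2)) + log(v1) + log(v2) - log(vs) -
      log(u2) - log(1 - u2^2) - log(u3) - log(1 - u3)

    if (log(stats::runif(1)) < loglik + log_prior + log_prop + log_jac) {
      ord <- order(c(m1, m2))
      new_mu <- append(mu[-j], c(m1, m2)[ord], after = j - 1)
      new_s2 <- append(s2[-j], c(v1, v2)[ord], after = j - 1)
      new_w <- append(w[-j], c(w1, w2)[ord], after = j - 1)
      new_z <- z
      new_z[z > j] <- new_z[z > j] + 1L
      first_is_1 <- ord[1] == 1
      new_z[idx] <- ifelse(assign1 == first_is_1, j, j + 1L)
      return(list(k = k + 1L, w = new_w, mu = new_mu, s2 = new_s2,
                  z = as.integer(new_z)))
    }
    return(keep)
  } else if (u0 < b_k + d_k) {
    # ---- merge (adjacent pair) ----
    j <- if (k == 2) 1L else sample.int(k - 1, 1)
    w1 <- w[j]; w2 <- w[j + 1]; m1 <- mu[j]; m2 <- mu[j + 1]
    v1 <- s2[j]; v2 <- s2[j + 1]
    ws <- w1 + w2
    ms <- (w1 * m1 + w2 * m2) / ws
    vs <- (w1 * (m1^2 + v1) + w2 * (m2^2 + v2)) / ws - ms^2
    # recover the u's of the reverse split
    u1 <- w1 / ws
    u2 <- (ms - m1) / (sqrt(vs) * sqrt(w2 / w1))
    if (u2 <= 0 || u2 >= 1 || vs <= 0) return(keep)
    u3 <- v1 * w1 / ((1 - u2^2) * vs * ws)
    if (u3 <= 0 || u3 >= 1) return(keep)

    idx <- which(z == j | z == j + 1L)
    in1 <- z[idx] == j
    l1 <- sum(in1); l2 <- sum(!in1)
    p1 <- w1 * exp(lphi(y[idx], m1, v1))
    p2 <- w2 * exp(lphi(y[idx], m2, v2))
    pr <- p1 / (p1 + p2)
    pr[is.na(pr)] <- 0.5
    la <- sum(log(ifelse(in1, pr, 1 - pr)))

    loglik <- sum(lphi(y[idx], m1, v1)[in1]) +
      sum(lphi(y[idx], m2, v2)[!in1]) - sum(lphi(y[idx], ms, vs))

    kk <- k - 1L  # k of the merged (smaller) state
    log_prior <- log(kk + 1) +
      (delta - 1 + l1) * log(w1) + (delta - 1 + l2) * log(w2) -
      (delta - 1 + l1 + l2) * log(ws) - lbeta(delta, kk * delta) +
      0.5 * log(kappa / (2 * pi)) -
      0.5 * kappa * ((m1 - xi)^2 + (m2 - xi)^2 - (ms - xi)^2) +
      alpha * log(beta) - lgamma(alpha) +
      (-alpha - 1) * (log(v1) + log(v2) - log(vs)) -
      beta * (1 / v1 + 1 / v2 - 1 / vs)

    b_prev <- 0.5  # split prob at k-1 (< kmax since we are at k <= kmax)
    d_here <- d_k
    log_prop <- log(d_here / b_prev) - la -
      stats::dbeta(u1, 2, 2, log = TRUE) -
      stats::dbeta(u2, 2, 2, log = TRUE) -
      stats::dbeta(u3, 1, 1, log = TRUE)
    log_jac <- log(ws) + log(abs(m1 - m2)) + log(v1) + log(v2) - log(vs) -
      log(u2) - log(1 - u2^2) - log(u3) - log(1 - u3)

    log_acc <- -(loglik + log_prior + log_prop + log_jac)
    if (log(stats::runif(1)) < log_acc) {
      new_mu <- mu[-(j + 1)]; new_mu[j] <- ms
      new_s2 <- s2[-(j + 1)]; new_s2[j] <- vs
      new_w <- w[-(j + 1)]; new_w[j] <- ws
      new_z <- z
      new_z[z == j + 1L] <- j
      new_z[z > j + 1L] <- new_z[z > j + 1L] - 1L
      return(list(k = kk, w = new_w, mu = new_mu, s2 = new_s2,
                  z = as.integer(new_z)))
    }
    return(keep)
  }
  keep
}

# birth/death of empty components. The newborn's mean and variance are drawn
# from the prior, so their prior density cancels against the proposal in the
# acceptance ratio.
move_birth_death <- function(n, k, w, mu, s2, z, nj, kmax, alpha, beta,
                             kappa, xi) {
  keep <- list(k = k, w = w, mu = mu, s2 = s2, z = z)
  b_k <- if (k < kmax) 0.5 else 0
  d_k <- if (k > 1) 0.5 else 0
  empties <- which(nj == 0)
  u0 <- stats::runif(1)
  if (u0 < b_k) {
    ws <- stats::rbeta(1, 1, k)
    k0 <- length(empties)
    log_acc <- n * log(1 - ws) + log(k + 1) - log(k0 + 1) + log(0.5 / b_k)
    if (log(stats::runif(1)) < log_acc) {
      m_new <- stats::rnorm(1, xi, 1 / sqrt(kappa))
      v_new <- 1 / stats::rgamma(1, alpha, rate = beta)
      pos <- sum(mu < m_new) + 1L
      new_mu <- append(mu, m_new, after = pos - 1)
      new_s2 <- append(s2, v_new, after = pos - 1)
      new_w <- append(w * (1 - ws), ws, after = pos - 1)
      new_z <- z
      new_z[z >= pos] <- new_z[z >= pos] + 1L
      return(list(k = k + 1L, w = new_w, mu = new_mu, s2 = new_s2,
                  z = as.integer(new_z)))
    }
  } else if (u0 < b_k + d_k && length(empties)) {
    j <- if (length(empties) == 1) empties else sample(empties, 1)
    ws <- w[j]
    e <- length(empties)
    b_prev <- 0.5  # birth prob at k-1
    log_acc <- -(n * log(1 - ws) + log(k) - log(e) + log(d_k / b_prev))
    if (log(stats::runif(1)) < log_acc) {
      new_w <- w[-j] / (1 - ws)
      new_mu <- mu[-j]; new_s2 <- s2[-j]
      new_z <- z
      new_z[z > j] <- new_z[z > j] - 1L
      return(list(k = k - 1L, w = new_w, mu = new_mu, s2 = new_s2,
                  z = as.integer(new_z)))
    }
  }
  keep
}

#' Count density modes of mixture draws
#'
#' Sensitivity variant: instead of counting components, count local maxima of
#' each retained draw's mixture density on a grid.
#'
#' @param posterior A \code{mixture_posterior}.
#' @param grid_n Grid resolution (default 512).
#' @return Integer vector of mode counts, one per retained draw.
#' @export
count_density_modes <- function(posterior, grid_n = 512) {
  vapply(posterior$draws, function(d) {
    lo <- min(d$mu - 4 * sqrt(d$s2)); hi <- max(d$mu + 4 * sqrt(d$s2))
    xs <- seq(lo, hi, length.out = grid_n)
    dens <- colSums(d$w * t(vapply(seq_along(d$mu), function(j)
      stats::dnorm(xs, d$mu[j], sqrt(d$s2[j])), numeric(grid_n))))
    sum(diff(sign(diff(dens))) == -2)
  }, integer(1))
}
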