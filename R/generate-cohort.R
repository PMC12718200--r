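# Inverse-CDF transform of a uniform draw under one marginal spec.
q_marginal <- function(u, spec, var) {
  switch(spec$family,
    normal = {
      lo <- spec$lower %||% -Inf
      hi <- spec$upper %||% Inf
      plo <- pnorm(lo, spec$mean, spec$sd)
      phi <- pnorm(hi, spec$mean, spec$sd)
      qnorm(plo + u * (phi - plo), spec$mean, spec$sd)
    },
    lognormal = qlnorm(u, spec$meanlog, spec$sdlog),
    zero_inflated_lognormal = {
      out <- numeric(length(u))
      pos <- u >= spec$p_zero
      out[pos] <- qlnorm((u[pos] - spec$p_zero) / (1 - spec$p_zero),
                         spec$meanlog, spec$sdlog)
      out
    },
    categorical = {
      probs <- spec$probs / sum(spec$probs)
      idx <- findInterval(u, cumsum(probs), left.open = TRUE) + 1L
      spec$levels[idx]
    },
    abort(sprintf("invalid distribution family '%s' for variable '%s'",
                  spec$family, var))
  )
}

# Draw an n x k matrix of correlated uniforms through a Gaussian copula.
# Variables inside a correlation block share an exchangeable correlation rho;
# everything else is independent.
copula_uniforms <- function(n, vars, blocks) {
  z <- matrix(rnorm(n * length(vars)), nrow = n,
              dimnames = list(NULL, vars))
  for (blk in blocks) {
    bv <- intersect(blk$vars, vars)
    k <- length(bv)
    if (k < 2 || blk$rho == 0) next
    sigma <- matrix(blk$rho, k, k)
    diag(sigma) <- 1
    z[, bv] <- z[, bv, drop = FALSE] %*% chol(sigma)
  }
  pnorm(z)
}

# Proportional-odds item machinery: items take values 0..K, generated as the
# number of thresholds exceeded by alpha + theta + logistic noise, where theta
# is a per-participant, per-domain latent severity. alpha is solved so the
# marginal item mean hits its target.
po_item_mean <- function(alpha, thresholds, theta_sd) {
  sum(vapply(thresholds, function(tau) {
    integrate(function(t) plogis(alpha + t - tau) * stats::dnorm(t, 0, theta_sd),
              -Inf, Inf)$value
  }, numeric(1)))
}

po_alpha_for_mean <- function(target_item_mean, thresholds, theta_sd = 1) {
  k <- length(thresholds)
  eps <- 1e-3
  target <- min(max(target_item_mean, eps), k - eps)
  uniroot(function(a) po_item_mean(a, thresholds, theta_sd) - target,
          interval = c(-20, 20))$root
}

# Generate an n x n_items matrix of ordinal responses for one domain.
generate_domain_items <- function(n, n_items, target_domain_mean, thresholds,
                                  theta_sd = 1) {
  alpha <- po_alpha_for_mean(target_domain_mean / n_items, thresholds, theta_sd)
  theta <- rnorm(n, 0, theta_sd)
  eta <- alpha + theta + matrix(rlogis(n * n_items), n, n_items)
  matrix(vapply(seq_len(n_items),
                function(j) rowSums(outer(eta[, j], thresholds, ">")),
                numeric(n)),
         nrow = n, ncol = n_items)
}

facit_domain_sizes <- function() {
  c(physical = 7, social = 7, emotional = 6, functional = 7, additional = 16)
}

#' Generate a seeded synthetic cohort
#'
#' Draws a cohort of participant records whose marginal distributions follow
#' the configuration (by default, the baseline structure of a severely obese
#' endometrial-cancer trial population: BMI truncated-normal 47.5 (9.3) with
#' minimum 30, 66% aged 50+, 78% physically inactive, lognormal intakes and
#' glycemic markers). Continuous variables are coupled through a Gaussian
#' copula; questionnaire items come from per-domain latent severities mapped
#' through proportional-odds thresholds, so planted domain means are
#' controllable. Weight is derived from BMI and height. FACIT items flagged
#' as reverse-scored in [default_facit_key()] are stored on the raw response
#' scale (4 minus the scored value), so scoring reproduces the generated
#' severities.
#'
#' The result is a deterministic function of the configuration, including its
#' seed.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per participant.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_participants
  withr::with_seed(config$seed, {
    vars <- names(config$marginals)
    u <- copula_uniforms(n, vars, config$correlations)
    cols <- purrr::imap(config$marginals, function(spec, nm) {
      q_marginal(u[, nm], spec, nm)
    })
    cohort <- tibble::as_tibble(cols)
    cohort$weight_kg <- cohort$bmi * (cohort$height_cm / 100)^2

    # FACIT: five domains, items 0..4 (thresholds tuned for a 0..4 scale).
    facit_thresholds <- c(-3, -1, 1, 3)
    fkey <- default_facit_key()
    sizes <- facit_domain_sizes()
    for (dom in names(sizes)) {
      m <- generate_domain_items(n, sizes[[dom]],
                                 config$facit_domain_means[[dom]],
                                 facit_thresholds)
      colnames(m) <- fkey$domains[[dom]]
      # store reverse-scored items on the raw response scale
      rev_cols <- intersect(colnames(m), fkey$reverse)
      m[, rev_cols] <- 4 - m[, rev_cols]
      cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(m))
    }

    # HADS: two 7-item subscales, items 0..3.
    hads_thresholds <- c(-2, 0, 2)
    for (dom in c("anxiety", "depression")) {
      m <- generate_domain_items(n, 7, config$hads_domain_means[[dom]],
                                 hads_thresholds)
      prefix <- if (dom == "anxiety") "hads_a" else "hads_d"
      colnames(m) <- paste0(prefix, 1:7)
      cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(m))
    }

    # variable-level missingness
    for (nm in names(config$missingness)) {
      rate <- config$missingness[[nm]]
      if (rate > 0 && nm %in% names(cohort)) {
        cohort[[nm]][runif(n) < rate] <- NA
      }
    }
    # item-level missingness
    if (config$item_missingness > 0) {
      item_cols <- grep("^(facit_|hads_)", names(cohort), value = TRUE)
      for (nm in item_cols) {
        cohort[[nm]][runif(n) < config$item_missingness] <- NA
      }
    }

    dplyr::bind_cols(tibble::tibble(id = sprintf("P%04d", seq_len(n))), cohort)
  })
}
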