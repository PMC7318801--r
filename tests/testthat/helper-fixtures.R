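# shared helpers: independent oracles and tiny generators

# brute-force order scanner, independent of validate_order: enumerates every
# run and every pair distance explicitly
brute_force_order_ok <- function(ids, items, max_run = 3, min_between = 6) {
  cong <- items$congruency[match(ids, items$item_id)]
  n <- length(ids)
  for (start in seq_len(n)) {
    len <- 1
    while (start + len <= n && cong[start + len] == cong[start]) {
      len <- len + 1
      if (len > max_run) return(FALSE)
    }
  }
  pair <- items$pair_id[match(ids, items$item_id)]
  for (p in unique(pair)) {
    pos <- which(pair == p)
    if (length(pos) == 2) {
      n_between <- abs(pos[2] - pos[1]) - 1
      if (n_between < min_between) return(FALSE)
    }
  }
  TRUE
}

# direct maximum-likelihood logistic fit by Newton-Raphson on the binomial
# log-likelihood; independent of glm()/glmer()
newton_logistic <- function(X, successes, weight, tol = 1e-12,
                            max_iter = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(t(X) %*% (successes - weight * mu))
    W <- weight * mu * (1 - mu)
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# participant table + deterministic grid values with no participant-level
# heterogeneity (random-effect variance truly zero in the generating model)
fixed_effects_fixture <- function(n_per_group = 10, weight = 20,
                                  b = c(0.4, -0.8, 0.6, -1.0)) {
  grp <- rep(c("side_effect", "means"), each = n_per_group)
  id <- sprintf("P%02d", seq_len(2 * n_per_group))
  long <- data.frame(
    participant_id = factor(rep(id, 2)),
    parameter = factor(rep(c("D", "U"), each = 2 * n_per_group),
                       levels = c("D", "U")),
    instrumentality = factor(rep(grp, 2),
                             levels = c("side_effect", "means")))
  X <- stats::model.matrix(~ parameter * instrumentality, long)
  p <- plogis(drop(X %*% b))
  # deterministic counts near the model surface, kept off the boundary;
  # the cyclic offset varies rows within each cell (identical responses
  # across a whole cell break the PIRLS step in lme4)
  long$successes <- pmin(pmax(as.integer(round(weight * p)) +
                                rep(c(-1L, 0L, 1L), length.out = nrow(long)),
                              1L),
                         weight - 1L)
  long$failures <- weight - long$successes
  long$value <- long$successes / weight
  long$weight <- weight
  long
}

# cohort with known latent values for closed-form checks
constant_cohort <- function(D, U, n = 50,
                            instrumentality = "means",
                            personal_force = "personal") {
  data.frame(participant_id = sprintf("C%04d", seq_len(n)),
             instrumentality = instrumentality,
             personal_force = personal_force,
             sex = "female",
             D_true = D, U_true = U,
             total_time = 1200,
             stringsAsFactors = FALSE)
}
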