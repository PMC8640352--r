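# Data-generating process and experiment runner: beta (or beta-mixture)
# latent traits, a Gaussian copula linking test and anchor, rounding to an
# integer score scale, a log-linear-smoothed "truth", multinomial
# replicate sampling, and per-replicate bandwidth selection / equating.

.shape_params <- list(
  symmetric = c(5, 5),
  neg_skew  = c(5, 2),
  pos_skew  = c(2, 5),
  bimodal   = NULL  # equal mixture of Beta(25, 15) and Beta(15, 25)
)

# Quantile transform of the latent-trait marginal; for the bimodal mixture
# the quantile is inverted numerically (vectorized bisection on [0, 1]).
.shape_quantile <- function(shape, u) {
  if (shape != "bimodal") {
    ab <- .shape_params[[shape]]
    return(qbeta(u, ab[1], ab[2]))
  }
  pmix <- function(x) 0.5 * pbeta(x, 25, 15) + 0.5 * pbeta(x, 15, 25)
  lo <- rep(0, length(u)); hi <- rep(1, length(u))
  for (i in seq_len(60)) {
    mid <- (lo + hi) / 2
    below <- pmix(mid) < u
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

# Fixed presmoothing designs mirroring the moment-preservation settings of
# the study conditions; `select_model()` offers the IC-searched alternative.
.truth_design <- function(design, shape, cross_variant = c("11_22", "all2")) {
  cross_variant <- match.arg(cross_variant)
  if (design == "eg") {
    list(degree = switch(shape, symmetric = 2, neg_skew = 3,
                         pos_skew = 3, bimodal = 3))
  } else {
    if (shape %in% c("symmetric", "neg_skew")) {
      cross <- if (cross_variant == "11_22") list(c(1, 1), c(2, 2))
               else list(c(1, 1), c(1, 2), c(2, 1))
      list(deg_x = 4, deg_a = 4, cross = cross)
    } else {
      list(deg_x = 2, deg_a = 2, cross = list(c(1, 1)))
    }
  }
}

#' Simulation scenario
#'
#' Describes one study condition: data-collection design, latent score
#' shape, group size, test and anchor lengths, copula correlation, the
#' score shift of population Q's form, and the replication count.
#'
#' @param design `"eg"` or `"neat"`.
#' @param shape `"symmetric"` (Beta(5,5)), `"neg_skew"` (Beta(5,2)),
#'   `"pos_skew"` (Beta(2,5)) or `"bimodal"` (equal mixture of Beta(25,15)
#'   and Beta(15,25)).
#' @param n Test takers per group.
#' @param items Test length J - 1 (scores 0..items), default 80.
#' @param anchor_items Anchor length L - 1 (NEAT only), default 20.
#' @param rho Gaussian-copula correlation between test and anchor latent
#'   traits (NEAT only), default 0.75.
#' @param q_shift Units added to population Q's form scores after
#'   rounding, clamped to the score grid (NEAT only), default 5.
#' @param G Number of Monte-Carlo replications, default 1000.
#' @param model_selection `"fixed"` uses the stated moment-preservation
#'   design for the shape; `"ic"` searches candidates by AIC (EG) / BIC
#'   (NEAT).
#' @param cross_variant Interpretation of "first and second cross-moment"
#'   for the symmetric / negatively skewed NEAT designs: `"11_22"` for
#'   orders (1,1) and (2,2), `"all2"` for (1,1), (1,2), (2,1).
#' @return An object of class `ke_scenario`.
#' @export
ke_scenario <- function(design = c("eg", "neat"),
                        shape = c("symmetric", "neg_skew", "pos_skew",
                                  "bimodal"),
                        n = 1000, items = 80, anchor_items = 20,
                        rho = 0.75, q_shift = 5, G = 1000,
                        model_selection = c("fixed", "ic"),
                        cross_variant = c("11_22", "all2")) {
  design <- match.arg(design)
  shape <- match.arg(shape)
  model_selection <- match.arg(model_selection)
  cross_variant <- match.arg(cross_variant)
  if (n < 2) stop("n must be at least 2")
  if (items < 2) stop("test length must be at least 2")
  if (design == "neat" && (rho <= -1 || rho >= 1)) {
    stop("copula correlation must lie in (-1, 1)")
  }
  structure(
    list(design = design, shape = shape, n = n, items = items,
         anchor_items = if (design == "neat") anchor_items else NULL,
         rho = if (design == "neat") rho else NULL,
         q_shift = if (design == "neat") q_shift else 0,
         G = G, model_selection = model_selection,
         cross_variant = cross_variant),
    class = "ke_scenario"
  )
}

#' @export
print.ke_scenario <- function(x, ...) {
  cat("<ke_scenario> ", toupper(x$design), ", ", x$shape, ", n = ", x$n,
      ", items = ", x$items,
      if (x$design == "neat") paste0(", anchor = ", x$anchor_items),
      ", G = ", x$G, "\n", sep = "")
  invisible(x)
}

.round_half_up <- function(x) floor(x + 0.5)

# One population draw of rounded scores; shift applies to the form score
# only (the anchor is the common instrument).
.draw_scores <- function(scenario, n, shift = 0) {
  J1 <- scenario$items
  if (scenario$design == "eg") {
    u <- .shape_quantile(scenario$shape, runif(n))
    x <- .round_half_up(J1 * u) + shift
    list(x = pmin(pmax(x, 0), J1))
  } else {
    rho <- scenario$rho
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    u <- .shape_quantile(scenario$shape, pnorm(z1))
    v <- .shape_quantile(scenario$shape, pnorm(z2))
    x <- .round_half_up(J1 * u) + shift
    a <- .round_half_up(scenario$anchor_items * v)
    list(x = pmin(pmax(x, 0), J1), a = a)
  }
}

.tab_univ <- function(x, J1) tabulate(match(x, 0:J1), nbins = J1 + 1)

.tab_biv <- function(x, a, J1, L1) {
  m <- matrix(0, J1 + 1, L1 + 1)
  for (i in seq_along(x)) m[x[i] + 1, a[i] + 1] <- m[x[i] + 1, a[i] + 1] + 1
  m
}

.fit_truth_univ <- function(counts, J1, scenario) {
  d <- score_dist(0:J1, counts = counts)
  if (scenario$model_selection == "ic") {
    select_model(d, criterion = "aic")
  } else {
    fit_loglinear_univariate(
      d, .truth_design("eg", scenario$shape)$degree)
  }
}

.fit_truth_biv <- function(counts, J1, L1, scenario) {
  tab <- biv_table(0:J1, 0:L1, counts = counts)
  if (scenario$model_selection == "ic") {
    select_model(tab, criterion = "bic")
  } else {
    des <- .truth_design("neat", scenario$shape, scenario$cross_variant)
    fit_loglinear_bivariate(tab, des$deg_x, des$deg_a, des$cross)
  }
}

#' Generate the true score probabilities of a scenario
#'
#' Draws one sample of latent traits per population, rounds to the score
#' grid, fits the scenario's log-linear design, and returns the strictly
#' positive fitted probabilities as the simulation truth. Performed once
#' per scenario; replicates are then multinomial draws from this truth.
#' A non-converging fit triggers a regeneration with a shifted seed (with
#' a message).
#'
#' @param scenario A [ke_scenario()].
#' @param seed Integer seed for the truth draw.
#' @return An object of class `ke_truth`: for EG, [score_dist()]s `r` and
#'   `s`; for NEAT, [biv_table()]s `P` (X, A) and `Q` (Y, A), plus the
#'   fitted design.
#' @export
generate_truth <- function(scenario, seed) {
  stopifnot(inherits(scenario, "ke_scenario"))
  J1 <- scenario$items
  for (attempt in seq_len(25)) {
    set.seed(seed + (attempt - 1) * 1000003)
    out <- tryCatch({
      if (scenario$design == "eg") {
        fx <- .fit_truth_univ(.tab_univ(.draw_scores(scenario, scenario$n)$x,
                                        J1), J1, scenario)
        fy <- .fit_truth_univ(.tab_univ(.draw_scores(scenario, scenario$n)$x,
                                        J1), J1, scenario)
        list(r = score_dist(0:J1, probs = fx$fitted_probs),
             s = score_dist(0:J1, probs = fy$fitted_probs),
             design = fx$design)
      } else {
        L1 <- scenario$anchor_items
        dp <- .draw_scores(scenario, scenario$n)
        fp <- .fit_truth_biv(.tab_biv(dp$x, dp$a, J1, L1), J1, L1, scenario)
        dq <- .draw_scores(scenario, scenario$n, shift = scenario$q_shift)
        fq <- .fit_truth_biv(.tab_biv(dq$x, dq$a, J1, L1), J1, L1, scenario)
        list(P = biv_table(0:J1, 0:L1, probs = fp$fitted_matrix),
             Q = biv_table(0:J1, 0:L1, probs = fq$fitted_matrix),
             design = fp$design)
      }
    }, error = function(e) e)
    if (!inherits(out, "error")) {
      out$scenario <- scenario
      out$seed <- seed + (attempt - 1) * 1000003
      class(out) <- "ke_truth"
      return(out)
    }
    message("truth generation attempt ", attempt, " failed (",
            conditionMessage(out), "); retrying with shifted seed")
  }
  stop("truth generation failed after 25 attempts")
}

#' Draw one replicate of observed frequencies from the truth
#'
#' @param truth A [generate_truth()] object.
#' @param n Test takers per group (defaults to the scenario's).
#' @param seed Integer seed.
#' @return For EG, list of [score_dist()]s `x`, `y` with counts; for NEAT,
#'   list of [biv_table()]s `P`, `Q` with counts.
#' @export
sample_replicate <- function(truth, n = truth$scenario$n, seed = NULL) {
  stopifnot(inherits(truth, "ke_truth"))
  if (!is.null(seed)) set.seed(seed)
  sc <- truth$scenario
  if (sc$design == "eg") {
    list(
      x = score_dist(truth$r$scores,
                     counts = as.numeric(rmultinom(1, n, truth$r$probs))),
      y = score_dist(truth$s$scores,
                     counts = as.numeric(rmultinom(1, n, truth$s$probs)))
    )
  } else {
    J <- length(truth$P$x_scores); L <- length(truth$P$a_scores)
    list(
      P = biv_table(truth$P$x_scores, truth$P$a_scores,
                    counts = matrix(rmultinom(1, n, truth$P$probs), J, L)),
      Q = biv_table(truth$Q$x_scores, truth$Q$a_scores,
                    counts = matrix(rmultinom(1, n, truth$Q$probs), J, L))
    )
  }
}

# Target-population score distributions implied by a truth object.
.truth_targets <- function(truth, weight = 0.5) {
  sc <- truth$scenario
  if (sc$design == "eg") {
    list(r = truth$r, s = truth$s)
  } else {
    design_function(ke_design("neat_pse", weight), truth$P, truth$Q)
  }
}

#' Run a full simulation scenario
#'
#' For each replicate: sample frequencies from the truth, presmooth with
#' the truth's log-linear design, map to target-population probabilities
#' (identity for EG; post-stratification with weight 0.5 for NEAT), select
#' the bandwidth(s) with each requested method, and (optionally) equate
#' X to Y. Aggregates mean/variance of the selected bandwidths, MSE of the
#' equated mean, per-score SE, PRE of the first ten moments of the mean
#' equated curve, and pairwise difference-that-matters counts.
#'
#' @param scenario A [ke_scenario()].
#' @param seed Master seed; deterministically expanded into the truth seed
#'   and per-replicate seeds.
#' @param methods Bandwidth selectors to run.
#' @param G Number of replications (defaults to the scenario's).
#' @param licv_repeats Split repeats for LiCV (default 100; 1000 matches
#'   the method's definition but is costly).
#' @param forms `"both"` selects bandwidths for X and Y and equates;
#'   `"x"` selects X bandwidths only (no equating).
#' @param weight NEAT target-population weight (default 0.5).
#' @param max_fail_frac Abort when more than this fraction of replicates
#'   fails (default 0.01).
#' @return An object of class `ke_sim_summary`.
#' @export
run_scenario <- function(scenario, seed = 1,
                         methods = c("penalty", "srt", "ds", "licv",
                                     "lcv", "plcv"),
                         G = scenario$G, licv_repeats = 100,
                         forms = c("both", "x"), weight = 0.5,
                         max_fail_frac = 0.01) {
  stopifnot(inherits(scenario, "ke_scenario"))
  methods <- match.arg(methods, .bw_methods, several.ok = TRUE)
  forms <- match.arg(forms)
  do_equating <- forms == "both"
  set.seed(seed)
  truth_seed <- sample.int(2^31 - 2, 1)
  rep_seeds <- sample.int(2^31 - 2, G)
  licv_seeds <- sample.int(2^31 - 2, G)
  truth <- generate_truth(scenario, truth_seed)
  targets <- .truth_targets(truth, weight)
  y_scores <- targets$s$scores
  mu_y_true <- sd_mean(targets$s)
  # the truth must not be the identity transformation
  phi_true <- ke_equate(targets$r, targets$s,
                        select_penalty(targets$r)$h,
                        select_penalty(targets$s)$h)$equated
  stopifnot(max(abs(phi_true - targets$r$scores)) > 0)

  J <- length(targets$r$scores)
  hx <- matrix(NA_real_, G, length(methods),
               dimnames = list(NULL, methods))
  hy <- if (do_equating) hx else NULL
  mu_hat <- if (do_equating) hx else NULL
  curves <- if (do_equating) {
    sapply(methods, function(m) matrix(NA_real_, G, J),
           simplify = FALSE)
  }
  failures <- 0L
  des <- truth$design

  for (g in seq_len(G)) {
    ok <- tryCatch({
      rep_data <- sample_replicate(truth, scenario$n, rep_seeds[g])
      if (scenario$design == "eg") {
        fx <- fit_loglinear_univariate(rep_data$x, des$degree)
        fy <- fit_loglinear_univariate(rep_data$y, des$degree)
        tg <- list(r = fitted_score_dist(fx), s = fitted_score_dist(fy))
        raw_x <- rep_data$x; raw_y <- rep_data$y
      } else {
        fp <- fit_loglinear_bivariate(rep_data$P, des$deg_x, des$deg_a,
                                      des$cross)
        fq <- fit_loglinear_bivariate(rep_data$Q, des$deg_x, des$deg_a,
                                      des$cross)
        tg <- design_function(ke_design("neat_pse", weight),
                              fitted_biv_table(fp), fitted_biv_table(fq))
        raw_x <- biv_margin(rep_data$P, "x")
        raw_y <- biv_margin(rep_data$Q, "x")
      }
      tg$r$n <- scenario$n; tg$s$n <- scenario$n
      licv_ic <- if (scenario$design == "eg") "aic" else "bic"
      for (m in methods) {
        hx[g, m] <- if (m == "licv") {
          select_licv(raw_x, n_repeats = licv_repeats,
                      seed = licv_seeds[g], presmooth = licv_ic)$h
        } else select_bandwidth(tg$r, m)$h
        if (do_equating) {
          hy[g, m] <- if (m == "licv") {
            select_licv(raw_y, n_repeats = licv_repeats,
                        seed = licv_seeds[g] + 1L, presmooth = licv_ic)$h
          } else select_bandwidth(tg$s, m)$h
          eqc <- ke_equate(tg$r, tg$s, hx[g, m], hy[g, m])$equated
          curves[[m]][g, ] <- eqc
          mu_hat[g, m] <- sum(eqc * targets$r$probs)
        }
      }
      TRUE
    }, error = function(e) {
      message("replicate ", g, " failed: ", conditionMessage(e))
      FALSE
    })
    if (!ok) failures <- failures + 1L
    if (failures > max_fail_frac * G && failures > 2L) {
      stop("too many replicate failures (", failures, " of ", g, ")")
    }
  }

  summ <- list(
    scenario = scenario, truth = truth, seed = seed, G = G,
    methods = methods, failures = failures,
    mean_h_x = colMeans(hx, na.rm = TRUE),
    var_h_x = apply(hx, 2, var, na.rm = TRUE),
    h_x = hx
  )
  if (do_equating) {
    summ$mean_h_y <- colMeans(hy, na.rm = TRUE)
    summ$h_y <- hy
    summ$mu_y_true <- mu_y_true
    summ$mu_hat <- mu_hat
    summ$mse <- apply(mu_hat, 2, function(v)
      mse_of_mean(v[!is.na(v)], mu_y_true))
    summ$se_curves <- lapply(curves, function(m)
      se_per_score(m[stats::complete.cases(m), , drop = FALSE]))
    summ$mean_curves <- lapply(curves, function(m)
      colMeans(m, na.rm = TRUE))
    summ$pre <- lapply(summ$mean_curves, function(cv)
      pre_moments(cv, targets$r$probs, y_scores, targets$s$probs, 10))
    nm <- length(methods)
    dtm <- matrix(0L, nm, nm, dimnames = list(methods, methods))
    for (i in seq_len(nm)) for (j in seq_len(nm)) {
      dtm[i, j] <- sum(dtm_compare(summ$mean_curves[[i]],
                                   summ$mean_curves[[j]]))
    }
    summ$dtm <- dtm
  }
  class(summ) <- "ke_sim_summary"
  summ
}

#' @export
print.ke_sim_summary <- function(x, ...) {
  cat("<ke_sim_summary> ", toupper(x$scenario$design), " ",
      x$scenario$shape, ", n = ", x$scenario$n, ", G = ", x$G,
      " (", x$failures, " failures)\n", sep = "")
  cat("  mean selected h_X:\n")
  print(round(x$mean_h_x, 3))
  if (!is.null(x$mse)) {
    cat("  MSE of the equated mean:\n")
    print(signif(x$mse, 4))
  }
  invisible(x)
}
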