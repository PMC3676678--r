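#' Branching times of an ultrametric tree
#'
#' Extracts internal-node ages (time before present), sorted descending,
#' after validating that the tree is binary and ultrametric.
#'
#' @param tree a `phylo` object, a newick string, or a newick file path.
#' @param tol ultrametricity tolerance as a fraction of the root age
#'   (default 1e-6).
#' @return object of class `branching_times`: list with `ages` (descending)
#'   and `n_tips`.
#' @export
branching_times <- function(tree, tol = 1e-6) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) stop("tree must be binary")
  depths <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  tip_depths <- depths[seq_len(ntip)]
  root_age <- max(tip_depths)
  if (diff(range(tip_depths)) > tol * root_age)
    stop("tree is not ultrametric within tolerance")
  ages <- sort(unname(ape::branching.times(tree)), decreasing = TRUE)
  structure(list(ages = ages, n_tips = ntip), class = "branching_times")
}

#' The six diversification models
#'
#' Model identifiers accepted by [fit_bdl()] and [model_select()].
#' @export
BDL_MODELS <- c("pureBirth", "birthDeath", "DDL", "DDX",
                "yule2rate", "yule3rate")

## Sufficient statistics of the waiting-time likelihood.
## ages descending t[1]..t[n-1]; interval with k lineages (k = 2..n-1) has
## length w[k-1] = t[k-1] - t[k], ends with a speciation at age t[k];
## terminal censored interval has n lineages and length t[n-1].
bt_stats <- function(bt) {
  t <- bt$ages; n <- bt$n_tips
  stopifnot(length(t) == n - 1L)
  k <- 2:(n - 1L)
  w <- -diff(t)                       # length n-2, matches k
  list(t = t, n = n, k = k, w = w, t_last = t[n - 1L],
       S = sum(k * w) + n * t[n - 1L],          # total lineage time
       E = n - 2L,                              # observed speciations
       sum_log_k = sum(log(k)))
}

RATE_MIN <- 1e-8
RATE_MAX <- 1e3

## generic waiting-time log-likelihood for per-lineage rate r(k)
loglik_rate_fn <- function(st, rate_of_k) {
  rk <- rate_of_k(st$k)               # rates during the k-lineage intervals
  rn <- rate_of_k(st$n)               # terminal interval rate
  if (any(rk <= 0) || rn < 0) return(-Inf)
  sum(log(st$k * rk)) - sum(st$k * rk * st$w) - st$n * rn * st$t_last
}

loglik_pure_birth <- function(st, r) {
  if (r <= 0) return(-Inf)
  st$sum_log_k + st$E * log(r) - r * st$S
}

## Nee-style constant birth-death likelihood on branching times, with
## r = net diversification and a = extinction fraction. Shares its a = 0
## limit (and additive constant) with the pure-birth waiting-time form.
loglik_birth_death <- function(st, r, a) {
  if (r <= 0 || a < 0 || a >= 1) return(-Inf)
  t <- st$t; n <- st$n
  ## log(exp(r t) - a) computed stably as r t + log1p(-a exp(-r t))
  lse <- r * t + log1p(-a * exp(-r * t))
  lfactorial(n - 1) + (n - 2) * log(r) + r * sum(t[-1]) +
    n * log(1 - a) - 2 * sum(lse)
}

fit_pure_birth <- function(st) {
  r <- min(max(st$E / st$S, RATE_MIN), RATE_MAX)
  list(params = c(r = r), logL = loglik_pure_birth(st, r), n_params = 1L)
}

fit_birth_death <- function(st, n_restarts = 5L) {
  obj <- function(p) -loglik_birth_death(st, exp(p[1L]), stats::plogis(p[2L]))
  r0 <- st$E / st$S
  starts <- rbind(c(log(r0), stats::qlogis(1e-4)),
                  c(log(r0), stats::qlogis(0.3)),
                  c(log(r0 * 2), stats::qlogis(0.6)),
                  c(log(r0 / 2), stats::qlogis(0.1)),
                  c(log(r0), stats::qlogis(0.9)))
  best <- NULL
  for (i in seq_len(min(n_restarts, nrow(starts)))) {
    fit <- tryCatch(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                                 lower = c(log(RATE_MIN), -20),
                                 upper = c(log(RATE_MAX), 20)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  r <- exp(best$par[1L]); a <- stats::plogis(best$par[2L])
  list(params = c(r = unname(r), a = unname(a)), logL = -best$value,
       n_params = 2L)
}

## DDX: r_k = r0 * k^(-x); r0 profiles out in closed form given x.
fit_ddx <- function(st) {
  prof <- function(x) {
    g <- sum(st$k^(1 - x) * st$w) + st$n^(1 - x) * st$t_last
    r0 <- st$E / g
    st$sum_log_k - x * sum(log(st$k)) + st$E * log(r0) - st$E
  }
  op <- stats::optimize(function(x) -prof(x), interval = c(-5, 5))
  x <- op$minimum
  g <- sum(st$k^(1 - x) * st$w) + st$n^(1 - x) * st$t_last
  r0 <- min(max(st$E / g, RATE_MIN), RATE_MAX)
  list(params = c(r0 = r0, x = x),
       logL = loglik_rate_fn(st, function(k) r0 * k^(-x)), n_params = 2L)
}

## DDL: r_k = r0 * (1 - k/K), K > n; r0 profiles out given K.
fit_ddl <- function(st) {
  n <- st$n
  prof_z <- function(z) {
    K <- n + exp(z)
    g <- sum(st$k * (1 - st$k / K) * st$w) + n * (1 - n / K) * st$t_last
    r0 <- st$E / g
    sum(log(st$k * (1 - st$k / K))) + st$E * log(r0) - st$E
  }
  op <- stats::optimize(function(z) -prof_z(z),
                        interval = c(log(1e-3), log(1e7)))
  K <- n + exp(op$minimum)
  g <- sum(st$k * (1 - st$k / K) * st$w) + n * (1 - n / K) * st$t_last
  r0 <- min(max(st$E / g, RATE_MIN), RATE_MAX)
  list(params = c(r0 = r0, K = K),
       logL = loglik_rate_fn(st, function(k) r0 * (1 - k / K)),
       n_params = 2L)
}

## Piecewise-constant pure-birth with shifts on the grid of observed
## branching times. Segment rate MLEs are closed form (events / lineage
## time), so the grid search is exact.
## Cumulative statistics above each candidate age t[m]:
##   events above t[m]: m - 2; lineage time above t[m]: C[m] = sum_{j<=m} j w_j.
fit_yule_multirate <- function(st, n_shifts) {
  n <- st$n
  t <- st$t
  ## C[m] for m = 2..n-1: lineage time older than age t[m]
  Cw <- c(0, cumsum(st$k * st$w))     # Cw[m] = lineage time older than t[m]
  C_at <- function(m) Cw[m]           # m in 2..n-1
  seg_ll <- function(E, Tm) {
    ## max_r E log r - r T with r in [RATE_MIN, RATE_MAX]
    r <- if (E == 0L) RATE_MIN else min(max(E / Tm, RATE_MIN), RATE_MAX)
    E * log(r) - r * Tm
  }
  best <- list(logL = -Inf)
  if (n_shifts == 1L) {
    for (m in 2:(n - 1L)) {
      T1 <- C_at(m); T2 <- st$S - T1
      E1 <- m - 2L; E2 <- st$E - E1
      ll <- st$sum_log_k + seg_ll(E1, T1) + seg_ll(E2, T2)
      if (ll > best$logL) {
        r1 <- if (E1 == 0L) RATE_MIN else min(max(E1 / T1, RATE_MIN), RATE_MAX)
        r2 <- if (E2 == 0L) RATE_MIN else min(max(E2 / T2, RATE_MIN), RATE_MAX)
        best <- list(logL = ll, params = c(r1 = r1, r2 = r2, st1 = t[m]))
      }
    }
    best$n_params <- 3L
  } else {
    for (m1 in 2:(n - 2L)) {
      T1 <- C_at(m1); E1 <- m1 - 2L
      for (m2 in (m1 + 1L):(n - 1L)) {
        T2 <- C_at(m2) - T1; E2 <- m2 - m1
        T3 <- st$S - C_at(m2); E3 <- st$E - E1 - E2
        ll <- st$sum_log_k + seg_ll(E1, T1) + seg_ll(E2, T2) + seg_ll(E3, T3)
        if (ll > best$logL) {
          rr <- vapply(list(c(E1, T1), c(E2, T2), c(E3, T3)), function(z)
            if (z[1L] == 0) RATE_MIN else
              min(max(z[1L] / z[2L], RATE_MIN), RATE_MAX), numeric(1))
          best <- list(logL = ll,
                       params = c(r1 = rr[1L], r2 = rr[2L], r3 = rr[3L],
                                  st1 = t[m1], st2 = t[m2]))
        }
      }
    }
    best$n_params <- 5L
  }
  best
}

#' Fit a birth-death-likelihood diversification model to branching times
#'
#' Six models are available: two rate-constant (`pureBirth`, `birthDeath`),
#' two density-dependent (`DDL` with a logistic rate `r0 (1 - k/K)`, `DDX`
#' with an exponential rate `r0 k^-x`), and two multi-rate pure-birth
#' variants (`yule2rate`, `yule3rate`) whose maximum-likelihood shift
#' times are searched on the grid of observed branching times (sufficient
#' for piecewise-constant rates). The likelihood is the waiting-time
#' (Nee-style) form conditioned on the root, including the censored
#' terminal interval; all six models share the same additive constant, so
#' AIC differences are directly comparable and the nestings
#' `pureBirth <= yule2rate <= yule3rate`, `pureBirth = DDX(x = 0)` hold
#' exactly.
#'
#' @param bt a `branching_times` object.
#' @param model one of `r paste0('"', BDL_MODELS, '"', collapse = ", ")`.
#' @return object of class `bdl_fit`: list with `model`, `params`, `logL`,
#'   `n_params`, `AIC`.
#' @export
fit_bdl <- function(bt, model = BDL_MODELS) {
  model <- match.arg(model)
  if (bt$n_tips < 4L) stop("need at least 4 tips")
  st <- bt_stats(bt)
  fit <- switch(model,
    pureBirth  = fit_pure_birth(st),
    birthDeath = fit_birth_death(st),
    DDX        = fit_ddx(st),
    DDL        = fit_ddl(st),
    yule2rate  = fit_yule_multirate(st, 1L),
    yule3rate  = fit_yule_multirate(st, 2L))
  structure(list(model = model, params = fit$params, logL = fit$logL,
                 n_params = fit$n_params,
                 AIC = 2 * fit$n_params - 2 * fit$logL),
            class = "bdl_fit")
}

#' Fit all diversification models and select by AIC
#'
#' Fits the requested models and reports the AIC difference between the
#' best rate-constant model (`pureBirth`, `birthDeath`) and the best
#' rate-variable model (`DDL`, `DDX`, `yule2rate`, `yule3rate`):
#' `delta_AIC_RC = AIC(best rate-constant) - AIC(best rate-variable)`.
#' Large positive values indicate support for rate variation.
#'
#' @param bt a `branching_times` object.
#' @param models character vector of models to fit (default all six).
#' @return object of class `bdl_model_selection`: list with `fits` (named
#'   list of `bdl_fit`), `table` (data.frame: model, logL, n_params, AIC,
#'   dAIC), `best_model`, `delta_AIC_RC`.
#' @export
model_select <- function(bt, models = BDL_MODELS) {
  rc <- intersect(models, c("pureBirth", "birthDeath"))
  rv <- intersect(models, c("DDL", "DDX", "yule2rate", "yule3rate"))
  if (length(rc) == 0L) stop("need at least one rate-constant model")
  fits <- lapply(models, function(m) fit_bdl(bt, m))
  names(fits) <- models
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  tab <- data.frame(model = models,
                    logL = vapply(fits, `[[`, numeric(1), "logL"),
                    n_params = vapply(fits, `[[`, integer(1), "n_params"),
                    AIC = aic, dAIC = aic - min(aic),
                    stringsAsFactors = FALSE)
  delta_rc <- if (length(rv)) min(aic[rc]) - min(aic[rv]) else NA_real_
  structure(list(fits = fits, table = tab,
                 best_model = models[which.min(aic)],
                 best_rc_model = rc[which.min(aic[rc])],
                 delta_AIC_RC = delta_rc),
            class = "bdl_model_selection")
}

#' @export
print.bdl_model_selection <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("best model: %s;  delta AIC_RC = %.3f\n",
              x$best_model, x$delta_AIC_RC))
  invisible(x)
}

## simulate one tree under the fitted best rate-constant model
simulate_null_tree <- function(fit, n_tips) {
  if (fit$model == "birthDeath" && fit$params[["a"]] > 0.05) {
    simulate_bd_tree(fit$params[["r"]], fit$params[["a"]], n_tips)
  } else {
    r <- fit$params[["r"]]
    simulate_yule_shift_tree(rates = r, n_tips = n_tips)
  }
}

## forward birth-death simulation conditioned (by rejection) on n
## surviving tips; birth lambda = r/(1-a), death mu = lambda a.
simulate_bd_tree <- function(r, a, n_tips, max_tries = 1000L) {
  lambda <- r / (1 - a); mu <- lambda * a
  for (try in seq_len(max_tries)) {
    tr <- try_simulate_bd(lambda, mu, n_tips)
    if (!is.null(tr)) return(tr)
  }
  stop("birth-death simulation failed to reach the requested tip count")
}

try_simulate_bd <- function(lambda, mu, n_tips) {
  ## lineages: parent internal node, birth time, alive flag
  n_int <- 1L
  int_edges <- list()
  par <- c(1L, 1L); born <- c(0, 0); alive <- c(TRUE, TRUE)
  dead_edges <- list()
  t <- 0
  repeat {
    k <- sum(alive)
    if (k == 0L) return(NULL)
    if (k >= n_tips) break
    t <- t + stats::rexp(1L, k * (lambda + mu))
    i <- which(alive)[sample.int(k, 1L)]
    if (stats::runif(1L) < lambda / (lambda + mu)) {
      n_int <- n_int + 1L
      int_edges[[length(int_edges) + 1L]] <- c(par[i], n_int, t - born[i])
      par <- c(par[-i], n_int, n_int); born <- c(born[-i], t, t)
      alive <- c(alive[-i], TRUE, TRUE)
    } else {
      dead_edges[[length(dead_edges) + 1L]] <- c(par[i], t - born[i])
      par <- par[-i]; born <- born[-i]; alive <- alive[-i]
    }
  }
  t_present <- t + stats::rexp(1L, sum(alive) * (lambda + mu))
  ## assemble survivors-only tree: drop extinct side branches by collapsing
  ## internal nodes with a single surviving descendant path.
  n <- sum(alive)
  ## count surviving children paths per internal node
  kids <- vector("list", n_int)
  for (e in int_edges) kids[[e[1L]]] <- c(kids[[e[1L]]], list(e))
  ## build survivor tree recursively from internal node 1
  tip_ct <- 0L
  edge <- matrix(0L, nrow = 0L, ncol = 2L); elen <- numeric(0)
  node_ct <- n + 1L
  ## children map: internal node -> list of (child internal, length) and tips
  tip_children <- vector("list", n_int)
  for (i in seq_along(par))
    tip_children[[par[i]]] <- c(tip_children[[par[i]]],
                                list(t_present - born[i]))
  build <- function(node) {
    ## returns list(id, extra_len) for the survivor subtree rooted here, or
    ## NULL if no survivors below
    branches <- list()
    for (e in kids[[node]] %||% list()) {
      sub <- build(e[2L])
      if (!is.null(sub)) {
        branches[[length(branches) + 1L]] <- list(id = sub$id,
                                                  len = sub$len + e[3L])
      }
    }
    for (tl in tip_children[[node]] %||% list()) {
      tip_ct <<- tip_ct + 1L
      branches[[length(branches) + 1L]] <- list(id = tip_ct, len = tl)
    }
    if (length(branches) == 0L) return(NULL)
    if (length(branches) == 1L)
      return(list(id = branches[[1L]]$id, len = branches[[1L]]$len))
    ## true bifurcation among survivors: create a node
    my_id <- node_ct + 1L
    node_ct <<- my_id
    for (b in branches) {
      edge <<- rbind(edge, c(my_id, b$id))
      elen <<- c(elen, b$len)
    }
    list(id = my_id, len = 0)
  }
  root_sub <- build(1L)
  if (is.null(root_sub) || tip_ct != n) return(NULL)
  ## renumber internal nodes so the root is n+1 (canonical ape form)
  internals <- sort(unique(edge[, 1L]))
  root_id <- setdiff(internals, edge[, 2L])
  remap <- stats::setNames(seq_along(internals) + n,
                           c(root_id, setdiff(internals, root_id)))
  e2 <- edge
  e2[, 1L] <- remap[as.character(edge[, 1L])]
  ii <- edge[, 2L] > n
  e2[ii, 2L] <- remap[as.character(edge[ii, 2L])]
  tr <- structure(list(edge = e2, edge.length = elen,
                       tip.label = sprintf("t%d", seq_len(tip_ct)),
                       Nnode = length(internals)), class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Parametric-bootstrap significance of the rate-shift statistic
#'
#' Simulates `n_boot` trees with the observed tip count under the best
#' rate-constant model's maximum-likelihood parameters, refits all models
#' to each, and reports the fraction of null `delta_AIC_RC` values at or
#' above the observed one.
#'
#' @param bt a `branching_times` object.
#' @param n_boot number of bootstrap replicates (default 500; below 100 a
#'   warning flag is set on the returned p-value).
#' @param seed integer seed.
#' @param models models included in the selection (default all six).
#' @return list with `p_value`, `observed` (delta AIC_RC), `null`
#'   (the bootstrap null distribution), `critical_95` (its 95th
#'   percentile), `low_boot_warning`.
#' @export
shift_significance <- function(bt, n_boot = 500L, seed = NULL,
                               models = BDL_MODELS) {
  set_seed_if_given(seed)
  sel <- model_select(bt, models)
  rc_fit <- sel$fits[[sel$best_rc_model]]
  null_delta <- vapply(seq_len(n_boot), function(b) {
    tr <- simulate_null_tree(rc_fit, bt$n_tips)
    model_select(branching_times(tr), models)$delta_AIC_RC
  }, numeric(1))
  list(p_value = mean(null_delta >= sel$delta_AIC_RC),
       observed = sel$delta_AIC_RC, null = null_delta,
       critical_95 = stats::quantile(null_delta, 0.95, names = FALSE),
       low_boot_warning = n_boot < 100L)
}
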