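#' Configuration for the belief-propagation sampler
#'
#' @param M Particles drawn per fate per pass (default 100, so each
#'   non-root internal node re-fits from up to `6 * M` particles).
#' @param T Maximum number of belief-propagation iterations. Convergence is
#'   typically reached within several hundred iterations; the default cap is
#'   1000.
#' @param em_max_iter Maximum EM iterations per mixture re-fit.
#' @param em_tol Absolute log-likelihood change below which EM stops.
#' @param var_floor_frac Standard-deviation floor, as a fraction of the
#'   initial sigma (the standard deviation of the tree's leaf expression
#'   values); prevents component collapse on point masses.
#' @param w_floor Lower bound on mixing weights during EM re-fits (default
#'   0.05). Keeps all three fate hypotheses alive: without it a component
#'   starved of particles in the diffuse early iterations dies (weight 0)
#'   and can never recover, collapsing the mixture.
#' @param em_init How each re-fit is initialized: `"warm"` (default)
#'   starts from the node's current mixture parameters, so successive
#'   re-estimates refine the same fate-indexed components; `"groups"`
#'   re-anchors every component to the moments of its fate's particle
#'   group each iteration.
#' @param weight_update When mixing weights are re-estimated: `"every"`
#'   (default) lets every EM re-fit update them; `"final"` keeps them
#'   pinned at the uniform fate prior 1/3 during the particle-passing
#'   iterations and frees them only in one final readout fit per node.
#' @param backward_bootstrap If `TRUE` (default), resample (bootstrap) each
#'   backward fate's feasible candidates up to `M`, so every fate
#'   contributes equal backward evidence (`3M` backward particles); if
#'   `FALSE`, guarded-out pairs are simply dropped.
#' @param estimate How the ancestral level is read off a node's mixture:
#'   `"mode"` (default) takes the component mean with the highest mixture
#'   density (the most likely expression level); `"weight"` takes the
#'   largest-weight component's mean (see [ancestral_estimate()]).
#' @param early_stop If `TRUE` (default), stop before `T` once every
#'   ancestral estimate has changed by less than `early_stop_tol`
#'   (relative) for `early_stop_window` consecutive iterations.
#' @param early_stop_tol Relative-change threshold for early stopping.
#' @param early_stop_window Consecutive stable iterations required.
#' @param seed Optional integer seed; with a fixed seed [run_nbp()] is
#'   bit-reproducible.
#' @return A list of class `nbp_config`.
#' @export
nbp_config <- function(M = 100L, T = 1000L, em_max_iter = 100L,
                       em_tol = 1e-6, var_floor_frac = 1e-3, w_floor = 0.05,
                       em_init = c("warm", "groups"),
                       weight_update = c("every", "final"),
                       backward_bootstrap = TRUE,
                       estimate = c("mode", "weight"),
                       early_stop = TRUE, early_stop_tol = 1e-3,
                       early_stop_window = 10L, seed = NULL) {
  em_init <- match.arg(em_init)
  weight_update <- match.arg(weight_update)
  estimate <- match.arg(estimate)
  stopifnot(M >= 1, T >= 1, em_max_iter >= 1, em_tol > 0,
            var_floor_frac > 0, w_floor >= 0, w_floor < 1 / 3,
            early_stop_window >= 1)
  structure(list(M = as.integer(M), T = as.integer(T),
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 var_floor_frac = var_floor_frac, w_floor = w_floor,
                 em_init = em_init, weight_update = weight_update,
                 backward_bootstrap = backward_bootstrap,
                 estimate = estimate, early_stop = early_stop,
                 early_stop_tol = early_stop_tol,
                 early_stop_window = as.integer(early_stop_window),
                 seed = seed),
            class = "nbp_config")
}

# floor for branch lengths entering a denominator (CF weighting)
.bl_floor <- 1e-6

# point value of a child for initialization: observed at leaves, the child's
# own CF (minimum-evolution) initial mean at internal nodes
.child_point <- function(tree, child_id, is_leaf, cf_init, index_of) {
  if (is_leaf) tree$leaf_values[child_id] else cf_init[index_of[child_id]]
}

#' Initialize per-node Gaussian mixtures
#'
#' Bottom-up pass: for each internal node the three component means are the
#' SF, CF and NF forward combinations of its children's point values (a leaf
#' child contributes its observed expression; an internal child its own
#' CF-initialized value). All component standard deviations start at the
#' standard deviation of the tree's leaf expression values (floored), and
#' mixing weights start uniform (a uniform prior over fates).
#'
#' @param tree A `paralog_tree` with leaf values attached.
#' @param config An [nbp_config()].
#' @return A list with 3-by-K matrices `w`, `mu`, `sigma` (rows SF, CF, NF;
#'   columns internal-node indices) and the scalar `sigma_floor`.
#' @export
init_gmms <- function(tree, config = nbp_config()) {
  stopifnot(inherits(tree, "paralog_tree"))
  if (is.null(tree$leaf_values)) stop("attach leaf expression values first",
                                      call. = FALSE)
  nt <- tree$nodes
  K <- nrow(nt)
  ntip <- length(tree$phy$tip.label)
  index_of <- integer(ntip + K)
  index_of[nt$node_id] <- nt$index
  sigma0 <- stats::sd(tree$leaf_values)
  if (!is.finite(sigma0)) sigma0 <- 0
  sigma_floor <- max(config$var_floor_frac * sigma0, 1e-8)
  sigma0 <- max(sigma0, sigma_floor)

  mu <- matrix(NA_real_, 3, K, dimnames = list(c("SF", "CF", "NF"), NULL))
  cf_init <- numeric(K)
  for (k in rev(seq_len(K))) { # youngest first: internal children ready
    va <- .child_point(tree, nt$child1[k], nt$child1_leaf[k], cf_init,
                       index_of)
    vb <- .child_point(tree, nt$child2[k], nt$child2_leaf[k], cf_init,
                       index_of)
    la <- max(nt$l1[k], .bl_floor)
    lb <- max(nt$l2[k], .bl_floor)
    mu[, k] <- c(va + vb, (lb * va + la * vb) / (la + lb), min(va, vb))
    cf_init[k] <- mu["CF", k]
  }
  list(w = matrix(1 / 3, 3, K, dimnames = dimnames(mu)),
       mu = mu,
       sigma = matrix(sigma0, 3, K, dimnames = dimnames(mu)),
       sigma_floor = sigma_floor)
}

#' Forward particle passing: children to parent
#'
#' Combines index-paired particles of the two duplicates into candidate
#' ancestral particles under each fate: `x_SF = a + b`,
#' `x_CF = (l_b * a + l_a * b) / (l_a + l_b)` (minimum-evolution weighting by
#' branch lengths), `x_NF = min(a, b)`.
#'
#' @param a,b Equal-length particle vectors of the two children (a leaf child
#'   contributes its constant observed value, replicated).
#' @param l_a,l_b Branch lengths (dS) from the parent to `a` and `b`.
#' @return A list with numeric vectors `sf`, `cf`, `nf` (each `length(a)`).
#' @export
#' @examples
#' forward_particles(50, 50, 1, 1) # list(sf = 100, cf = 50, nf = 50)
forward_particles <- function(a, b, l_a, l_b) {
  stopifnot(length(a) == length(b))
  l_a <- max(l_a, .bl_floor)
  l_b <- max(l_b, .bl_floor)
  list(sf = a + b,
       cf = (l_b * a + l_a * b) / (l_a + l_b),
       nf = pmin(a, b))
}

#' Backward particle passing: parent and sibling to a node
#'
#' Given index-paired particles of the parent `x` and the sibling `a`,
#' produces candidate particles for the node `b` under each fate. SF requires
#' `x > a` (`b = x - a`); NF requires `x < a` (`b = x`); pairs violating a
#' guard contribute no particle for that fate. The CF candidate
#' `b = ((l_a + l_b) * x - l_b * a) / l_a` is likewise infeasible when
#' negative (expression is nonnegative) and such pairs are dropped.
#'
#' @param x,a Equal-length particle vectors of the parent and the sibling.
#' @param l_a Branch length from the parent to the sibling `a`.
#' @param l_b Branch length from the parent to this node `b`.
#' @return A list with numeric vectors `sf`, `cf`, `nf`, each possibly
#'   shorter than `length(x)` (guarded pairs dropped).
#' @export
#' @examples
#' backward_particles(100, 30, 1, 1) # sf = 70, cf = 170, nf = numeric(0)
backward_particles <- function(x, a, l_a, l_b) {
  stopifnot(length(x) == length(a))
  l_a <- max(l_a, .bl_floor)
  l_b <- max(l_b, .bl_floor)
  cf <- ((l_a + l_b) * x - l_b * a) / l_a
  list(sf = (x - a)[x > a],
       cf = cf[cf >= 0],
       nf = x[x < a])
}

#' Re-fit a 3-component Gaussian mixture by EM
#'
#' Warm-started univariate EM with a standard-deviation floor. The M-step is
#' the floor-constrained maximizer, so the per-iteration log-likelihood is
#' non-decreasing. With fewer than 3 particles the previous mixture is kept
#' (with a warning).
#'
#' @param particles Numeric vector of nonnegative particles.
#' @param init List with numeric length-3 `w`, `mu`, `sigma` (the node's
#'   current mixture; components are fate-indexed SF, CF, NF).
#' @param max_iter,tol EM iteration cap and absolute log-likelihood
#'   convergence tolerance.
#' @param sigma_floor Lower bound for component standard deviations.
#' @param w_floor Lower bound for mixing weights (see [nbp_config()]); 0
#'   disables it.
#' @return A list with `w`, `mu`, `sigma`, the per-iteration `loglik` trace,
#'   and `iterations`.
#' @export
fit_gmm_em <- function(particles, init, max_iter = 100L, tol = 1e-6,
                       sigma_floor = 1e-8, w_floor = 0) {
  stopifnot(is.list(init), all(c("w", "mu", "sigma") %in% names(init)))
  if (length(particles) < 3) {
    warning("fewer than 3 particles; keeping previous mixture",
            call. = FALSE)
    return(list(w = init$w, mu = init$mu, sigma = init$sigma,
                loglik = numeric(0), iterations = 0L))
  }
  em_gmm3_cpp(as.numeric(particles), as.numeric(init$w),
              as.numeric(init$mu), as.numeric(init$sigma),
              as.integer(max_iter), tol, sigma_floor, w_floor)
}

#' Ancestral expression estimate from a mixture
#'
#' The most likely expression level under the node's belief. With `sigma`
#' supplied (the default path in [run_nbp()]), the estimate is the component
#' mean at which the full mixture density is highest -- the expression level
#' of highest likelihood given the mixture. This coincides with the
#' largest-weight component when spreads are comparable, but correctly
#' prefers a sharp, well-supported component over a diffuse one that happens
#' to hold more weight. Without `sigma`, the largest-weight component wins;
#' components whose means coincide (within 1e-9 relative) describe a single
#' density, so their weights are summed first -- the CF and NF candidate
#' values coincide exactly whenever a node's two children have equal values,
#' making those two components exact twins. All ties break toward the
#' larger mean.
#'
#' @param w,mu Numeric length-3 mixing weights and component means.
#' @param sigma Optional component standard deviations; when given, the
#'   estimate is the highest-density component mean (approximate mixture
#'   mode).
#' @return A single expression level.
#' @export
#' @examples
#' ancestral_estimate(c(0.52, 0.30, 0.18), c(263.8, 90, 50)) # 263.8
#' ancestral_estimate(c(0.4, 0.3, 0.3), c(100, 50, 50)) # 50: twins sum to 0.6
#' # with spreads, the most likely expression level (mixture mode):
#' ancestral_estimate(c(0.6, 0.05, 0.35), c(290, 650, 150), c(160, 360, 0.1))
ancestral_estimate <- function(w, mu, sigma = NULL) {
  if (is.null(sigma)) {
    eps <- 1e-9 * pmax(1, abs(mu))
    grp_w <- vapply(seq_along(mu), function(i) {
      sum(w[abs(mu - mu[i]) <= eps[i]])
    }, numeric(1))
    cand <- which(grp_w == max(grp_w))
    return(mu[cand[which.max(mu[cand])]])
  }
  dens <- vapply(mu, function(m) {
    sum(w * stats::dnorm(m, mu, sigma))
  }, numeric(1))
  cand <- which(dens >= max(dens) * (1 - 1e-9))
  mu[cand[which.max(mu[cand])]]
}

#' Run nonparametric belief propagation on a paralog tree
#'
#' Each internal node carries a 3-component Gaussian mixture (one component
#' per fate, weights starting uniform -- a uniform prior over fates). Per
#' iteration: `M` particles are drawn from every internal node's mixture
#' (truncated at 0 by rejection, since expression is nonnegative); every
#' node collects `3M` forward candidates from its children's particles
#' ([forward_particles()]; leaf children contribute their constant observed
#' value) and every non-root node additionally collects up to `3M` backward
#' candidates from its parent's and sibling's particles
#' ([backward_particles()], feasible candidates bootstrap-resampled to `M`
#' per fate by default); each node's mixture is then re-fit by warm-started
#' EM with a variance floor and a mixing-weight floor ([fit_gmm_em()]). The
#' root has no parent and re-fits from its `3M` forward particles alone.
#' Ancestral levels are read off as the most likely expression level under
#' each node's final mixture ([ancestral_estimate()]).
#'
#' @param tree A `paralog_tree` with leaf values attached.
#' @param config An [nbp_config()].
#' @return An object of class `nbp_fit`: the final mixtures (3-by-K matrices
#'   `w`, `mu`, `sigma`), per-node ancestral `estimates`, iteration count,
#'   convergence flag, and bookkeeping (`min_em_loglik_step`, the most
#'   negative per-fit relative log-likelihood increment observed, which EM
#'   theory bounds at 0 up to floating-point round-off). Methods: [tidy()], [glance()],
#'   [infer_fates()], [autoplot()].
#' @export
#' @examples
#' tr <- read_paralog_trees(text = "((g1:1,g2:1):1,g3:1);")[[1]]
#' tr <- set_leaf_values(tr, c(g1 = 50, g2 = 50, g3 = 200))
#' fit <- run_nbp(tr, nbp_config(M = 50, T = 50, seed = 1))
#' fit$estimates
run_nbp <- function(tree, config = nbp_config()) {
  stopifnot(inherits(tree, "paralog_tree"))
  if (is.null(tree$leaf_values)) stop("attach leaf expression values first",
                                      call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  nt <- tree$nodes
  K <- nrow(nt)
  M <- config$M
  ntip <- length(tree$phy$tip.label)
  index_of <- integer(ntip + K)
  index_of[nt$node_id] <- nt$index
  mix <- init_gmms(tree, config)
  sigma_floor <- mix$sigma_floor

  # hot-loop locals: plain vectors are much cheaper than tibble columns
  ch1 <- nt$child1; ch1_leaf <- nt$child1_leaf
  ch2 <- nt$child2; ch2_leaf <- nt$child2_leaf
  bl1 <- nt$l1; bl2 <- nt$l2
  par_idx <- nt$parent_index
  sib <- nt$sib_id; sib_leaf <- nt$sib_leaf
  l_sib <- nt$l_sib; l_self <- nt$l_self

  # constant particle vectors for leaves
  leaf_const <- lapply(seq_len(ntip), function(i) rep(tree$leaf_values[i], M))
  particles_of <- function(id, is_leaf, draws) {
    if (is_leaf) leaf_const[[id]] else draws[[index_of[id]]]
  }

  node_estimates <- function() {
    vapply(seq_len(K), function(k) {
      if (config$estimate == "mode") {
        ancestral_estimate(mix$w[, k], mix$mu[, k], mix$sigma[, k])
      } else {
        ancestral_estimate(mix$w[, k], mix$mu[, k])
      }
    }, numeric(1))
  }
  est <- node_estimates()
  stable <- 0L
  converged <- FALSE
  min_ll_step <- 0
  iter <- 0L
  pin_w <- config$weight_update == "final"

  draw_particles <- function() {
    draws <- vector("list", K)
    for (k in seq_len(K)) {
      comp <- sample.int(3L, M, replace = TRUE, prob = mix$w[, k])
      d <- stats::rnorm(M, mix$mu[comp, k], mix$sigma[comp, k])
      # particles are expression levels: sample the mixture truncated at 0
      # by rejection (component means are nonnegative, so acceptance >= 1/2;
      # clamping instead would pile an atom at 0 that captures a component)
      neg <- which(d < 0)
      while (length(neg) > 0) {
        d[neg] <- stats::rnorm(length(neg), mix$mu[comp[neg], k],
                               mix$sigma[comp[neg], k])
        neg <- neg[d[neg] < 0]
      }
      draws[[k]] <- d
    }
    draws
  }

  make_groups <- function(draws) {
    groups <- vector("list", K)
    for (k in seq_len(K)) {
      a <- particles_of(ch1[k], ch1_leaf[k], draws)
      b <- particles_of(ch2[k], ch2_leaf[k], draws)
      fwd <- forward_particles(a, b, bl1[k], bl2[k])
      g <- list(sf = fwd$sf, cf = fwd$cf, nf = fwd$nf)
      if (!is.na(par_idx[k])) {
        x <- draws[[par_idx[k]]]
        s <- particles_of(sib[k], sib_leaf[k], draws)
        bwd <- backward_particles(x, s, l_sib[k], l_self[k])
        if (config$backward_bootstrap) {
          # equalize: M backward particles per fate, resampling feasible
          # candidates; a fate with no feasible pair contributes none
          bwd <- lapply(bwd, function(v) {
            if (length(v) == 0 || length(v) == M) v
            else v[sample.int(length(v), M, replace = TRUE)]
          })
        }
        g <- list(sf = c(g$sf, bwd$sf), cf = c(g$cf, bwd$cf),
                  nf = c(g$nf, bwd$nf))
      }
      groups[[k]] <- g
    }
    groups
  }

  refit <- function(groups, fix_weights) {
    for (k in seq_len(K)) {
      g <- groups[[k]]
      pool_k <- c(g$sf, g$cf, g$nf)
      if (length(pool_k) < 3) next # keep previous mixture
      if (config$em_init == "groups") {
        # EM initialized from the fate-tagged particle groups, anchoring
        # each component to its fate's candidate cluster; an empty or
        # singleton group falls back to the component's current parameters
        ng <- lengths(g)
        mu0 <- vapply(seq_len(3L), function(j) {
          if (ng[j] >= 1) mean(g[[j]]) else mix$mu[j, k]
        }, numeric(1))
        sd0 <- vapply(seq_len(3L), function(j) {
          if (ng[j] >= 2) stats::sd(g[[j]]) else mix$sigma[j, k]
        }, numeric(1))
        if (fix_weights) {
          w0 <- rep(1 / 3, 3)
        } else {
          w0 <- pmax(ng / length(pool_k), max(config$w_floor, 1e-3))
          w0 <- w0 / sum(w0)
        }
      } else { # warm start from the node's current mixture
        mu0 <- mix$mu[, k]
        sd0 <- mix$sigma[, k]
        w0 <- mix$w[, k]
      }
      f <- em_gmm3_cpp(pool_k, w0, mu0, pmax(sd0, sigma_floor),
                       config$em_max_iter, config$em_tol, sigma_floor,
                       config$w_floor, fix_weights)
      if (f$iterations > 1) {
        # relative step: monotone up to round-off at the likelihood's scale
        rel <- diff(f$loglik) / pmax(1, abs(f$loglik[-f$iterations]))
        min_ll_step <<- min(min_ll_step, min(rel))
      }
      mix$w[, k] <<- f$w
      mix$mu[, k] <<- f$mu
      mix$sigma[, k] <<- f$sigma
    }
  }

  for (t in seq_len(config$T)) {
    iter <- t
    refit(make_groups(draw_particles()), fix_weights = pin_w)
    est_new <- node_estimates()
    if (config$early_stop) {
      rel <- abs(est_new - est) / pmax(abs(est), 1e-12)
      stable <- if (all(rel < config$early_stop_tol)) stable + 1L else 0L
      est <- est_new
      if (stable >= config$early_stop_window) {
        converged <- TRUE
        break
      }
    } else {
      est <- est_new
    }
  }
  if (pin_w) {
    # readout pass: one extra particle pass with the mixing weights freed,
    # giving each fate component its data-determined weight
    refit(make_groups(draw_particles()), fix_weights = FALSE)
  }
  est <- node_estimates()

  structure(list(tree = tree, w = mix$w, mu = mix$mu, sigma = mix$sigma,
                 estimates = est, iterations = iter, converged = converged,
                 sigma_floor = sigma_floor,
                 min_em_loglik_step = min_ll_step, config = config),
            class = "nbp_fit")
}

#' @export
print.nbp_fit <- function(x, ...) {
  cat("<nbp_fit> ", nrow(x$tree$nodes), " internal nodes, ",
      x$iterations, " iterations",
      if (x$converged) " (converged early)" else "", "\n", sep = "")
  est <- round(x$estimates, 1)
  cat("  ancestral estimates: ",
      paste0("node ", seq_along(est), " = ", est, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn run_nbp Per-component mixture parameters as a tibble
#'   (`node_index`, `fate`, `weight`, `mean`, `sd`, `estimate`).
#' @param x An `nbp_fit`.
#' @param ... Unused.
#' @export
tidy.nbp_fit <- function(x, ...) {
  K <- ncol(x$w)
  tibble::tibble(
    node_index = rep(seq_len(K), each = 3L),
    fate = rep(c("SF", "CF", "NF"), K),
    weight = as.numeric(x$w),
    mean = as.numeric(x$mu),
    sd = as.numeric(x$sigma),
    estimate = rep(x$estimates, each = 3L)
  )
}

#' @describeIn run_nbp One-row fit summary.
#' @export
glance.nbp_fit <- function(x, ...) {
  tibble::tibble(
    n_leaves = length(x$tree$phy$tip.label),
    n_internal = nrow(x$tree$nodes),
    layers = n_layers(x$tree),
    iterations = x$iterations,
    converged = x$converged,
    M = x$config$M,
    T_max = x$config$T,
    min_em_loglik_step = x$min_em_loglik_step
  )
}

#' Classify the fate of every duplication event in a fitted tree
#'
#' For each internal node builds the (ancestor, duplicate, duplicate) triple
#' from the node's ancestral estimate and its children's values (observed at
#' leaves, estimated at internal nodes), then applies [classify_fate()].
#' All-zero triples are flagged `unclassifiable` rather than failing.
#'
#' @param fit An `nbp_fit` from [run_nbp()].
#' @return A tibble with one row per internal node: `node_index`, the triple
#'   `x`, `a`, `b`, and the classification columns of [classify_fate()].
#' @export
infer_fates <- function(fit) {
  stopifnot(inherits(fit, "nbp_fit"))
  nt <- fit$tree$nodes
  ntip <- length(fit$tree$phy$tip.label)
  index_of <- integer(ntip + nrow(nt))
  index_of[nt$node_id] <- nt$index
  child_val <- function(id, is_leaf) {
    if (is_leaf) fit$tree$leaf_values[id] else fit$estimates[index_of[id]]
  }
  a <- unname(mapply(child_val, nt$child1, nt$child1_leaf))
  b <- unname(mapply(child_val, nt$child2, nt$child2_leaf))
  dplyr::bind_cols(
    tibble::tibble(node_index = nt$index, x = fit$estimates, a = a, b = b),
    classify_fate(fit$estimates, a, b, on_zero = "na")
  )
}
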