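#' Fitting configuration
#'
#' @param n_restarts Random restarts of the optimizer (best kept).
#' @param max_iterations Maximum quasi-Newton iterations per restart.
#' @param tol Relative objective-change convergence tolerance.
#' @param seed Integer seed controlling restart initialization.
#' @param run_average Average across runs before fitting (default; per-run
#'   fitting is obtained by passing single-run data or `FALSE`).
#' @param rho_max Spectral-radius barrier for the output weighting matrix.
#' @param chunk Iterations per objective-trace checkpoint.
#' @return A `fit_config` list.
#' @export
fit_config <- function(n_restarts = 5, max_iterations = 500, tol = 1e-6,
                       seed = 0, run_average = TRUE, rho_max = 0.95,
                       chunk = 50) {
  abort_if(tol <= 0, "tol must be > 0")
  abort_if(n_restarts < 1, "n_restarts must be >= 1")
  structure(list(n_restarts = n_restarts, max_iterations = max_iterations,
                 tol = tol, seed = seed, run_average = run_average,
                 rho_max = rho_max, chunk = chunk),
            class = "fit_config")
}

# Coerce a tidy time-course tibble (or matrix) for one analysis unit into
# a regions-by-time matrix ordered by the network's region list.
tc_matrix <- function(data, net, run_average = TRUE) {
  if (is.matrix(data)) {
    abort_if(is.null(rownames(data)) || !all(net$regions %in% rownames(data)),
             "matrix input must have all network regions as rownames")
    return(data[net$regions, , drop = FALSE])
  }
  abort_if(!is.data.frame(data), "data must be a data frame or matrix")
  abort_if(!all(c("region", "t", "bold") %in% names(data)),
           "data needs columns region, t, bold")
  for (col in c("participant", "condition", "group")) {
    if (col %in% names(data) && length(unique(data[[col]])) > 1) {
      stop("data contains multiple ", col,
           "s; fit one analysis unit at a time (see fit_sapm_groups)",
           call. = FALSE)
    }
  }
  if ("run" %in% names(data) && length(unique(data$run)) > 1) {
    abort_if(!run_average,
             "multiple runs supplied with run_average = FALSE; fit runs separately")
    data <- dplyr::summarise(
      dplyr::group_by(data, .data$region, .data$t),
      bold = mean(.data$bold), .groups = "drop"
    )
  }
  miss <- setdiff(net$regions, unique(data$region))
  abort_if(length(miss) > 0,
           paste0("missing time courses for region(s): ",
                  paste(miss, collapse = ", ")))
  d <- data[data$region %in% net$regions, c("region", "t", "bold")]
  w <- tidyr::pivot_wider(dplyr::arrange(d, .data$t),
                          names_from = "t", values_from = "bold")
  m <- as.matrix(w[, -1])
  rownames(m) <- w$region
  m[net$regions, , drop = FALSE]
}

# Connections whose B value influences some observable signal. A B value
# only enters the likelihood through the target region's *output* signal;
# if that region has no outgoing edges its output reaches no observable,
# so the connection's B (hence DB) is structurally non-identified.
identified_connections <- function(net) {
  has_output <- net$regions %in% net$edges$from
  names(has_output) <- net$regions
  unname(has_output[connection_targets(net)])
}

#' Which connection weightings can this network identify?
#'
#' The latent-driven linear model constrains the data only through the
#' region-by-latent gain matrix applied to freely estimated latent time
#' courses, so not every connection's weighting is recoverable from time
#' series. Two failure modes are detected:
#' \describe{
#'   \item{`sink`}{the target region has no outgoing edges, so its output
#'     signal -- the only place this B value enters -- reaches no
#'     observable. The B value carries exactly zero information and is
#'     fixed at 0 during fitting; DB is reported `NA`.}
#'   \item{`degenerate`}{the connection participates in an exact
#'     trade-off: a direction in parameter space along which the fit is
#'     unchanged (the latent estimates absorb the move). Typical causes:
#'     a region whose inputs' outputs are collinear because they descend
#'     from the same latent chain, or a network with more weightings than
#'     the latent-subspace geometry can pin down. These weightings are
#'     estimated and reported but individual values are not trustworthy
#'     (only combinations are).}
#' }
#' Degeneracy is assessed generically: the numerical null space of the
#' Jacobian of the gain map at several random parameter draws. Weightings
#' outside the null space are reported `identified`; note that some may
#' still carry little curvature (wide sampling spread) in very small or
#' chain-like networks -- group-mean estimates and the null-simulation
#' tests remain the meaningful statistics.
#'
#' @param net A `bold_network`.
#' @param n_probe Random parameter draws for the generic rank analysis.
#' @param seed Seed for the draws.
#' @return Tibble with columns `connection`, `status`
#'   (`identified`/`degenerate`/`sink`), `identified` (logical, status ==
#'   "identified").
#' @export
connection_identifiability <- function(net, n_probe = 3, seed = 7919) {
  labels <- connection_labels(net)
  D <- uniform_D(net)
  free <- identified_connections(net)
  status <- ifelse(free, "identified", "sink")
  free_i <- which(free)
  K <- nrow(net$latents)
  if (length(free_i) > 0 && K > 0) {
    gain_of <- function(B) {
      forward_gain(build_matrices(net, D, setNames(B, labels)))
    }
    degen <- rep(FALSE, length(free_i))
    for (pr in seq_len(n_probe)) {
      B <- with_seed(child_seed(seed, pr), {
        b <- runif(length(labels), -0.6, 0.6)
        b[!free] <- 0
        b
      })
      mats <- build_matrices(net, D, setNames(B, labels))
      if (spectral_radius(mats$M_output) >= 0.9) next
      J <- vapply(free_i, function(j) {
        h <- 1e-6
        Bp <- B; Bp[j] <- Bp[j] + h
        Bm <- B; Bm[j] <- Bm[j] - h
        as.vector(gain_of(Bp) - gain_of(Bm)) / (2 * h)
      }, numeric(length(net$regions) * K))
      sv <- svd(J)
      null_v <- sv$v[, sv$d < 1e-8 * max(sv$d, 1e-12), drop = FALSE]
      if (ncol(null_v)) {
        degen <- degen | apply(abs(null_v) > 1e-5, 1, any)
      }
    }
    status[free_i[degen]] <- "degenerate"
  }
  tibble::tibble(connection = labels, status = status,
                 identified = status == "identified")
}

# Profiled objective/gradient factory. Latent time courses are solved
# exactly by linear least squares inside every objective evaluation, so
# the quasi-Newton steps on B act on the profiled objective; by the
# envelope theorem its gradient equals the fixed-latent gradient.
make_objective <- function(Y, net, D, rho_max) {
  R <- length(net$regions)
  ne <- nrow(net$edges)
  K <- nrow(net$latents)
  ti <- match(net$edges$to, net$regions)
  si <- match(net$edges$from, net$regions)
  lt <- match(net$latents$target, net$regions)
  De <- D[seq_len(ne)]
  Dl <- D[ne + seq_len(K)]
  M_input <- matrix(0, R, R)
  if (ne) M_input[cbind(ti, si)] <- De
  Lat_D <- matrix(0, R, K)
  Lat_D[cbind(lt, seq_len(K))] <- Dl
  I_R <- diag(R)
  ridge <- diag(1e-10, K)
  penalty <- function(rho) 1e8 * (1 + rho - rho_max)

  eval_state <- function(B) {
    M <- matrix(0, R, R)
    if (ne) M[cbind(ti, si)] <- De * B[seq_len(ne)]
    Lat_DB <- matrix(0, R, K)
    Lat_DB[cbind(lt, seq_len(K))] <- Dl * B[ne + seq_len(K)]
    rho <- spectral_radius(M)
    if (rho >= rho_max) return(list(bad = TRUE, rho = rho))
    S <- solve(I_R - M)
    MS <- M_input %*% S
    G <- MS %*% Lat_DB + Lat_D
    U <- solve(crossprod(G) + ridge, crossprod(G, Y))
    Res <- Y - G %*% U
    list(bad = FALSE, M = M, Lat_DB = Lat_DB, S = S, MS = MS, G = G,
         U = U, Res = Res, obj = sum(Res * Res))
  }

  fn <- function(B) {
    st <- eval_state(B)
    if (st$bad) return(penalty(st$rho))
    st$obj
  }
  gr <- function(B) {
    st <- eval_state(B)
    if (st$bad) return(numeric(ne + K))
    tMSR <- crossprod(st$MS, st$Res)            # R x T
    g <- numeric(ne + K)
    if (ne) {
      S_out <- st$S %*% st$Lat_DB %*% st$U      # R x T
      A <- tMSR %*% t(S_out)                    # A[t, s]
      g[seq_len(ne)] <- -2 * De * A[cbind(ti, si)]
    }
    Cl <- tMSR %*% t(st$U)                      # R x K
    g[ne + seq_len(K)] <- -2 * Dl * Cl[cbind(lt, seq_len(K))]
    g
  }
  list(fn = fn, gr = gr, eval_state = eval_state,
       dims = list(R = R, ne = ne, K = K))
}

#' Fit the latent-input signaling model to regional time courses
#'
#' Estimates, for one analysis unit (one chosen sub-region time course per
#' region; typically the run-averaged course of one participant and
#' condition), the signed conversion factors B of every connection and the
#' latent input time courses, minimizing the summed squared difference
#' between the observed courses and the model's region input signal. D
#' values are fixed by uniform row-normalization (see [uniform_D()]).
#' Because each latent also contributes directly to its target region's
#' input signal with weight D, the latent time courses' scale and sign
#' are identified by the data (no arbitrary normalization is applied);
#' the generator emits latents on a unit-variance scale and fits recover
#' that scale. The reported per-edge statistic is DB = D x B.
#'
#' Optimization: the latent time courses are profiled out exactly by
#' linear least squares within every objective evaluation and the B vector
#' is updated by quasi-Newton (BFGS) steps with an analytic gradient,
#' restarted from `n_restarts` random initializations; the best objective
#' is kept and the objective checkpoint trace is non-increasing by
#' construction.
#'
#' @param data Tidy tibble with columns `region`, `t`, `bold` (single
#'   participant/condition; runs are averaged when `cfg$run_average`), or
#'   a regions-by-time matrix with region rownames.
#' @param net A `bold_network` (must have at least one latent input).
#' @param cfg A [fit_config()].
#' @return An object of class `sapm_fit`; see [tidy.sapm_fit()] and
#'   [glance.sapm_fit()].
#' @export
#' @examples
#' net <- network_model(c("A", "B"), data.frame(from = "A", to = "B"),
#'                      data.frame(name = "L", target = "A"))
#' cfgs <- sim_config(net, n_participants = c(HC = 1), n_runs = 1,
#'                    noise_sd = 0, initial_rise = list(amplitude = 0))
#' tc <- simulate_bold(cfgs, make_paradigm("Pain", TR = 2, run_duration = 120))
#' fit <- fit_sapm(tc, net, fit_config(n_restarts = 2))
#' tidy(fit)
fit_sapm <- function(data, net, cfg = fit_config()) {
  stopifnot(inherits(net, "bold_network"))
  abort_if(nrow(net$latents) < 1,
           "network has no latent inputs; the model has no drive to fit")
  Y <- tc_matrix(data, net, run_average = cfg$run_average)
  abort_if(any(!is.finite(Y)), "non-finite values in time courses")
  Y <- Y - rowMeans(Y)
  Tn <- ncol(Y)
  ne <- nrow(net$edges)
  K <- nrow(net$latents)
  p <- ne + K
  # structurally non-identified B values are fixed at 0 and reported NA;
  # degenerate (trade-off) weightings are estimated but flagged
  idstat <- connection_identifiability(net)
  free <- identified_connections(net)
  if (Tn < 3 * sum(free)) {
    warning(sprintf("time length %d < 3 x %d free parameters; fit may be unstable",
                    Tn, sum(free)), call. = FALSE)
  }
  D <- uniform_D(net)
  ob <- make_objective(Y, net, D, cfg$rho_max)
  expand <- function(par) {
    B <- numeric(p)
    B[free] <- par
    B
  }
  fn_free <- function(par) ob$fn(expand(par))
  gr_free <- function(par) ob$gr(expand(par))[free]

  if (sum(free) == 0) {
    # nothing to optimize: all B fixed at 0, latents solved directly
    best <- list(B = numeric(0), obj = ob$fn(numeric(p)),
                 traj = ob$fn(numeric(p)), converged = TRUE)
    converged_any <- TRUE
  } else {
  best <- NULL
  converged_any <- FALSE
  for (r in seq_len(cfg$n_restarts)) {
    B <- with_seed(child_seed(cfg$seed, r), {
      b <- runif(p, -0.5, 0.5)
      b[ne + seq_len(K)] <- runif(K, 0.3, 1.0)  # positive latent drive init
      b[!free] <- 0
      b
    })[free]
    obj_prev <- fn_free(B)
    obj_scale <- max(sum(Y * Y), 1e-300)
    traj <- obj_prev
    converged <- FALSE
    iters_left <- cfg$max_iterations
    while (iters_left > 0) {
      step <- min(cfg$chunk, iters_left)
      res <- tryCatch(
        optim(B, fn_free, gr_free, method = "BFGS",
              control = list(maxit = step, reltol = cfg$tol * 1e-2)),
        error = function(e) NULL
      )
      if (is.null(res) || !is.finite(res$value)) break
      if (res$value > obj_prev) {  # stalled: optimizer cannot improve
        converged <- TRUE
        break
      }
      B <- res$par
      traj <- c(traj, res$value)
      rel <- (obj_prev - res$value) / max(obj_prev, 1e-300)
      obj_prev <- res$value
      iters_left <- iters_left - step
      if (rel < cfg$tol || obj_prev <= 1e-12 * obj_scale) {
        converged <- TRUE
        break
      }
    }
    if (is.null(best) || obj_prev < best$obj) {
      best <- list(B = B, obj = obj_prev, traj = traj, converged = converged)
    }
    converged_any <- converged_any || converged
  }
  }
  if (!converged_any) {
    warning("no optimizer restart met the convergence tolerance", call. = FALSE)
  }

  # latent scale and sign are identified by the direct D-weighted latent
  # input term, so no post-hoc normalization is applied
  B <- expand(best$B)
  st <- ob$eval_state(B)
  U <- st$U
  names(B) <- connection_labels(net)
  mats <- build_matrices(net, D = D, B = B)
  fwd <- solve_forward(mats, U)
  Res <- Y - fwd$S_input
  fit_error <- sum(Res^2)
  sstot <- rowSums(Y^2)
  R2 <- ifelse(sstot > 0, 1 - rowSums(Res^2) / sstot, NA_real_)
  rownames(U) <- net$latents$name

  connections <- tibble::tibble(
    connection = connection_labels(net),
    from = c(net$edges$from, net$latents$name),
    to = c(net$edges$to, net$latents$target),
    type = c(rep("edge", ne), rep("latent", K)),
    status = idstat$status,
    identified = idstat$identified,
    D = unname(D),
    B = ifelse(free, unname(B), NA_real_),
    DB = ifelse(free, unname(D * B), NA_real_)
  )
  structure(
    list(network = net, connections = connections, latents = U,
         S_output = fwd$S_output, S_input = fwd$S_input,
         observed = Y, residuals = Res, fit_error = fit_error,
         R2 = tibble::tibble(region = net$regions, R2 = unname(R2),
                             flag = ifelse(sstot > 0, "", "zero-variance")),
         objective_trace = best$traj, converged = converged_any,
         config = cfg),
    class = "sapm_fit"
  )
}

#' @export
print.sapm_fit <- function(x, ...) {
  cat(sprintf(
    "<sapm_fit> %s: %d connections, fit error %.4g, mean R2 %.3f%s\n",
    x$network$name, nrow(x$connections), x$fit_error,
    mean(x$R2$R2, na.rm = TRUE),
    if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' Tidy and summarize fitted signaling models
#'
#' `tidy()` returns one row per connection with the fitted D, B and DB
#' values; `glance()` returns a one-row model summary.
#'
#' @param x An `sapm_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy sapm_fit
#' @export
tidy.sapm_fit <- function(x, ...) {
  x$connections
}

#' @rdname tidy.sapm_fit
#' @method glance sapm_fit
#' @export
glance.sapm_fit <- function(x, ...) {
  tibble::tibble(
    fit_error = x$fit_error,
    mean_R2 = mean(x$R2$R2, na.rm = TRUE),
    min_R2 = min(x$R2$R2, na.rm = TRUE),
    n_regions = length(x$network$regions),
    n_connections = nrow(x$connections),
    n_latents = nrow(x$network$latents),
    converged = x$converged
  )
}

#' Per-region variance explained
#'
#' The proportion of variance in each region's (sub-region) time course
#' explained by the network model: `R2 = 1 - SS_resid / SS_total`.
#' Zero-variance regions are flagged and return `NA`.
#'
#' @param fit An `sapm_fit`.
#' @return Tibble with columns `region`, `R2`, `flag`.
#' @export
fit_quality <- function(fit) {
  stopifnot(inherits(fit, "sapm_fit"))
  fit$R2
}

#' Fit the model per participant and condition
#'
#' Averages runs within each participant/condition, fits the network
#' model, and returns the per-connection DB values -- the inputs to the
#' group-level statistics.
#'
#' @param data Tidy time-course tibble with `participant`, `group`,
#'   `condition`, `run`, `region`, `t`, `bold`.
#' @param net A `bold_network`.
#' @param cfg A [fit_config()].
#' @return Tibble: `participant`, `group`, `condition`, `connection`,
#'   `type`, `D`, `B`, `DB`, `fit_error`, `mean_R2`, `converged`.
#' @export
fit_sapm_groups <- function(data, net, cfg = fit_config()) {
  groups <- dplyr::group_by(data, .data$participant, .data$group,
                            .data$condition)
  keys <- dplyr::group_keys(groups)
  fits <- dplyr::group_split(groups)
  out <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    f <- fit_sapm(fits[[i]], net, cfg)
    out[[i]] <- dplyr::mutate(
      tidy(f),
      participant = keys$participant[i], group = keys$group[i],
      condition = keys$condition[i], fit_error = f$fit_error,
      mean_R2 = mean(f$R2$R2, na.rm = TRUE), converged = f$converged,
      .before = 1
    )
  }
  dplyr::bind_rows(out)
}
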