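#' Greedily match embedding components to ground-truth maps
#'
#' Computes the 2 x 2 correlations between connectopic components and
#' ground-truth maps, matches the pair with the largest absolute correlation
#' first, then matches the remaining pair — guaranteeing each component is
#' matched to exactly one map even when both components correlate best with
#' the same map. Ties are broken in favour of the eccentricity (first) map,
#' then the first component.
#'
#' @param e Embedding: a [cnp_embedding()] or an `n x 2` matrix.
#' @param g Ground truth: an `n x 2` matrix (columns eccentricity, polar) or
#'   a [make_retinotopic_grid()] result.
#' @return A tibble with one row per matched pair: `component`, `map`,
#'   `map_type`, `r` (signed), `abs_r`, ordered by `map`.
#' @export
match_components <- function(e, g) {
  em <- if (inherits(e, "cnp_embedding")) e$components else check_matrix(e, "e")
  gm <- if (inherits(g, "cnp_grid")) ground_truth_maps(g) else check_matrix(g, "g")
  if (nrow(em) != nrow(gm)) abort("embedding and ground truth must share vertex order")
  if (nrow(em) < 3) abort("need at least 3 vertices")
  if (any(apply(em, 2, sd) == 0)) abort("embedding has a constant component")
  if (any(apply(gm, 2, sd) == 0)) abort("ground-truth map is constant")
  map_names <- colnames(gm) %||% c("ecc", "polar")
  r_mat <- cor(em, gm)                       # components x maps
  n_pair <- min(ncol(em), ncol(gm))
  comp_left <- seq_len(ncol(em)); map_left <- seq_len(ncol(gm))
  out <- vector("list", n_pair)
  for (p in seq_len(n_pair)) {
    sub <- abs(r_mat[comp_left, map_left, drop = FALSE])
    # ties: prefer the first (eccentricity) map, then the first component
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, "col"], best[, "row"]), , drop = FALSE][1, ]
    ci <- comp_left[best[["row"]]]; mi <- map_left[best[["col"]]]
    rv <- unname(r_mat[ci, mi])
    out[[p]] <- tibble(component = ci, map = mi,
                       map_type = map_names[mi],
                       r = rv, abs_r = abs(rv))
    comp_left <- setdiff(comp_left, ci); map_left <- setdiff(map_left, mi)
  }
  bind_rows(out) |> arrange(.data$map)
}

#' Prediction accuracy of a connectopic embedding
#'
#' The benchmark score: the absolute Pearson correlation between each
#' matched connectopic/ground-truth map pair (absolute, to absorb the sign
#' ambiguity of the components). Extra label columns (subject, task,
#' algorithm, ...) can be supplied and are attached to every record.
#'
#' @inheritParams match_components
#' @param ... Named scalar labels added as columns (e.g. `algorithm = "pca"`).
#' @return A tibble with one row per map: `map_type` (`"eccentricity"` /
#'   `"polar"` for the standard two maps), `abs_r`, plus any labels.
#' @export
prediction_accuracy <- function(e, g, ...) {
  matched <- match_components(e, g)
  std_names <- c("eccentricity", "polar")
  if (nrow(matched) == 2) matched$map_type <- std_names[matched$map]
  labels <- list(...)
  res <- matched |> select("map_type", "abs_r")
  if (length(labels)) res <- res |> mutate(!!!labels, .before = 1)
  res
}

#' Reliability of connectopic maps across splits or tasks
#'
#' Matches the components of one embedding to another by the same greedy
#' rule used against ground truth, and reports the absolute correlation per
#' matched pair. `split_half_reliability()` is meant for the odd/even run
#' splits of one task; `cross_task_reliability()` for embeddings from
#' different tasks (e.g. odd resting-state vs even movie-watching runs).
#' Both are invariant to component sign flips in either argument.
#'
#' @param e1,e2 Two embeddings ([cnp_embedding()] or `n x 2` matrices) over
#'   the same vertex order.
#' @return A tibble with `component` (of `e1`), `abs_r`.
#' @export
split_half_reliability <- function(e1, e2) {
  m1 <- if (inherits(e1, "cnp_embedding")) e1$components else check_matrix(e1, "e1")
  matched <- match_components(e2, m1)
  tibble(component = matched$map, abs_r = matched$abs_r)
}

#' @rdname split_half_reliability
#' @export
cross_task_reliability <- function(e1, e2) split_half_reliability(e1, e2)

# ---- Gaussian-process Bayesian optimisation ---------------------------------

# map unit-cube coordinates to native parameter values
decode_params <- function(u, defs) {
  vals <- lapply(seq_along(defs), function(j) {
    d <- defs[[j]]
    v <- if (d$log) exp(log(d$lower) + u[j] * (log(d$upper) - log(d$lower)))
         else d$lower + u[j] * (d$upper - d$lower)
    if (d$integer) as.integer(round(v)) else v
  })
  setNames(vals, map(defs, "name"))
}

# expected improvement from a fixed-hyperparameter Gaussian-process surrogate
gp_propose <- function(u_obs, y_obs, candidates, lengthscale = 0.2) {
  ys <- (y_obs - mean(y_obs)) / max(sd(y_obs), 1e-12)
  kfun <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  kmat <- kfun(u_obs, u_obs) + diag(1e-4, nrow(u_obs))
  kinv_y <- solve(kmat, ys)
  kstar <- kfun(candidates, u_obs)
  mu <- as.vector(kstar %*% kinv_y)
  kv <- solve(kmat, t(kstar))
  s2 <- pmax(1 - colSums(t(kstar) * kv), 1e-12)
  s <- sqrt(s2)
  best <- max(ys)
  z <- (mu - best - 0.01) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  candidates[which.max(ei), , drop = FALSE]
}

#' Cross-validated Bayesian parameter selection
#'
#' Selects an algorithm's free parameters on one data split by maximising
#' the mean absolute correlation between the two matched
#' connectopic/ground-truth maps, via Gaussian-process Bayesian optimisation
#' with a fixed per-parameter budget: `budget` total evaluations of which
#' `n_random` are space-filling random starts, per free parameter (defaults
#' 100 and 10). Trials whose graph is disconnected (or that otherwise fail)
#' score `-Inf` and are excluded from the surrogate. The selected parameters
#' are meant to be applied to the held-out split.
#'
#' @param algorithm One of [list_algorithms()].
#' @param x Fingerprints of the training split.
#' @param g Ground truth (`n x 2` matrix or grid).
#' @param budget Iterations per free parameter, random starts included.
#' @param n_random Random starts per free parameter.
#' @param seed Integer seed.
#' @return A list of class `cnp_opt`: `params` (named list), `objective`,
#'   `trace` (tibble of every trial), `algorithm`.
#' @export
crossval_optimize <- function(algorithm, x, g, budget = 100, n_random = 10,
                              seed = 1) {
  x <- as_matrix_input(x)
  defs <- algorithm_params(algorithm, x)
  d <- length(defs)
  if (d == 0) {
    return(structure(list(params = list(), objective = NA_real_,
                          trace = tibble(), algorithm = algorithm),
                     class = "cnp_opt"))
  }
  total <- budget * d
  n_start <- min(n_random * d, total)
  objective <- function(params) {
    tryCatch({
      emb <- embed_algorithm(x, algorithm, params, seed = seed)
      mean(match_components(emb, g)$abs_r)
    }, error = function(e) -Inf)
  }
  u_all <- matrix(NA_real_, total, d)
  y_all <- rep(NA_real_, total)
  with_seed_(child_seed(seed, 97), {
    u_all[seq_len(n_start), ] <- lhs::randomLHS(n_start, d)
    for (i in seq_len(total)) {
      if (i > n_start) {
        ok <- is.finite(y_all[seq_len(i - 1)])
        if (!any(ok)) {
          u_all[i, ] <- runif(d)
        } else {
          cand <- rbind(matrix(runif(200 * d), ncol = d),
                        pmin(pmax(matrix(rep(u_all[which.max(y_all), ], 50),
                                         ncol = d, byrow = TRUE) +
                                  matrix(rnorm(50 * d, sd = 0.05), ncol = d),
                                  0), 1))
          u_all[i, ] <- gp_propose(u_all[seq_len(i - 1), , drop = FALSE][ok, , drop = FALSE],
                                   y_all[seq_len(i - 1)][ok], cand)
        }
      }
      y_all[i] <- objective(decode_params(u_all[i, ], defs))
    }
  })
  if (!any(is.finite(y_all))) {
    abort("all optimisation trials were invalid (disconnected graphs?)",
          class = "cnp_all_trials_invalid")
  }
  best <- which.max(y_all)
  pm <- do.call(rbind, lapply(seq_len(total), function(i) {
    unlist(decode_params(u_all[i, ], defs))
  }))
  colnames(pm) <- vapply(defs, `[[`, character(1), "name")
  trace <- as_tibble(as.data.frame(pm)) |>
    mutate(iteration = dplyr::row_number(), objective = y_all,
           valid = is.finite(y_all), .before = 1)
  structure(list(params = decode_params(u_all[best, ], defs),
                 objective = y_all[best], trace = trace,
                 algorithm = algorithm),
            class = "cnp_opt")
}

#' @export
print.cnp_opt <- function(x, ...) {
  cat(sprintf("<cnp_opt> %s: best objective %.4f at {%s} (%d trials)\n",
              x$algorithm, x$objective,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = " = ", collapse = ", "),
              nrow(x$trace)))
  invisible(x)
}

#' @export
tidy.cnp_opt <- function(x, ...) x$trace

#' @export
glance.cnp_opt <- function(x, ...) {
  tibble(algorithm = x$algorithm, objective = x$objective,
         n_trials = nrow(x$trace),
         n_invalid = if (nrow(x$trace)) sum(!x$trace$valid) else 0L)
}

# translate a user-facing source-mode label into build_connectivity() args
source_mode_args <- function(source_mode) {
  if (source_mode == "within_roi_pca") {
    list(mode = "within_roi", within_roi_pca = TRUE)
  } else {
    list(mode = source_mode, within_roi_pca = FALSE)
  }
}

#' Run the full benchmark for one subject
#'
#' Orchestrates the pipeline end to end for one (synthetic or real) subject:
#' partition the recording into odd/even runs, build fingerprints per split
#' and source mode, select parameters on one split by [crossval_optimize()],
#' embed the held-out split with the selected parameters, and score against
#' ground truth. Parameters are never fitted on the split they are evaluated
#' on. By default both cross-fitting directions are run (optimise on odd,
#' test on even, and vice versa).
#'
#' @param roi_ts ROI [cnp_timeseries()] (multi-run).
#' @param sources Named list of non-ROI [cnp_timeseries()] blocks (`cortex`,
#'   `subcortex`) on the same run structure.
#' @param truth Ground-truth `n x 2` matrix or [make_retinotopic_grid()].
#' @param algorithms Character vector from [list_algorithms()].
#' @param source_modes Character vector from `"all"`, `"cortex"`,
#'   `"subcortex"`, `"noise"`, `"within_roi"`, `"within_roi_pca"`.
#' @param task Label recorded on every row (e.g. `"movie"`).
#' @param subject Subject label recorded on every row.
#' @param seed Integer seed controlling every stochastic stage.
#' @param budget,n_random Optimiser budget per free parameter
#'   (see [crossval_optimize()]).
#' @param directions `"both"` for the two cross-fitting directions, or
#'   `"single"` for optimise-on-odd / test-on-even only.
#' @param keep_embeddings Attach the test-split embeddings (for reliability
#'   analyses) as attribute `"embeddings"`.
#' @return A tibble of accuracy records, one row per (algorithm, source
#'   mode, direction, map): columns `subject`, `task`, `algorithm`,
#'   `source_mode`, `split`, `map_type`, `abs_r`.
#' @export
run_subject <- function(roi_ts, sources, truth, algorithms = "spectral_knn_unweighted",
                        source_modes = "all", task = "movie", subject = "s01",
                        seed = 1, budget = 100, n_random = 10,
                        directions = c("both", "single"),
                        keep_embeddings = FALSE) {
  directions <- rlang::arg_match(directions)
  gm <- if (inherits(truth, "cnp_grid")) ground_truth_maps(truth) else check_matrix(truth, "truth")
  splits <- split_odd_even(roi_ts)
  src_splits <- lapply(sources, split_odd_even)
  half <- function(which) lapply(src_splits, `[[`, which)
  fp <- list()
  for (mode in source_modes) {
    args <- source_mode_args(mode)
    fp[[mode]] <- lapply(c(odd = "odd", even = "even"), function(w) {
      build_connectivity(splits[[w]], half(w), mode = args$mode,
                         seed = child_seed(seed, 11 + (w == "even")),
                         within_roi_pca = args$within_roi_pca, split_id = w)
    })
  }
  dir_tbl <- tibble(train = c("odd", "even"), test = c("even", "odd"))
  if (directions == "single") dir_tbl <- dir_tbl[1, ]
  records <- list(); embeddings <- list()
  combo <- 0
  for (mode in source_modes) {
    for (alg in algorithms) {
      for (j in seq_len(nrow(dir_tbl))) {
        combo <- combo + 1
        cseed <- child_seed(seed, 100 + combo)
        opt <- crossval_optimize(alg, fp[[mode]][[dir_tbl$train[j]]], gm,
                                 budget = budget, n_random = n_random,
                                 seed = cseed)
        emb <- embed_algorithm(fp[[mode]][[dir_tbl$test[j]]], alg,
                               opt$params, seed = cseed)
        key <- paste(mode, alg, dir_tbl$test[j], sep = ".")
        embeddings[[key]] <- emb
        records[[key]] <- prediction_accuracy(
          emb, gm, subject = subject, task = task, algorithm = alg,
          source_mode = mode, split = dir_tbl$test[j])
      }
    }
  }
  out <- bind_rows(records)
  if (keep_embeddings) attr(out, "embeddings") <- embeddings
  out
}
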