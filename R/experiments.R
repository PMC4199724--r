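#' Configure a parameter sweep
#'
#' A sweep runs `replicates` searches in every cell of the grid over `N`,
#' `p` and `K` and aggregates them with [summarize_runs()].  Per-run seeds
#' are derived as `base_seed + 10000 * cell_index + replicate_index`
#' (cells in grid row order), so a sweep is exactly reproducible from its
#' config; keep `replicates < 10000` and `base_seed` small so derived
#' seeds stay below 2^31.
#'
#' @param puzzle a [parse_puzzle()] object.
#' @param N,p numeric vectors of grid values.
#' @param K `"full"` for the fully connected system (`K = N - 1` in every
#'   cell) or a numeric vector; cells with `K > N - 1` or with `p > 0,
#'   K = 0` are dropped with a warning.
#' @param replicates searches per cell (>= 2).
#' @param base_seed integer.
#' @param max_trials per-run cap (NULL for the [search_params()] default).
#' @param move_kind `"elementary"` or `"global"`.
#' @return an object of class `sweep_config`.
#' @export
sweep_config <- function(puzzle, N, p, K = "full", replicates = 1000L,
                         base_seed = 1L, max_trials = NULL,
                         move_kind = "elementary") {
  stopifnot(inherits(puzzle, "puzzle"), replicates >= 2L)
  if (identical(K, "full")) {
    grid <- expand.grid(N = N, p = p)
    grid$K <- grid$N - 1L
  } else {
    grid <- expand.grid(N = N, p = p, K = K)
    bad <- grid$K > grid$N - 1L | (grid$p > 0 & grid$K < 1L)
    if (any(bad)) {
      warning("dropping ", sum(bad), " infeasible grid cells")
      grid <- grid[!bad, , drop = FALSE]
    }
  }
  bad2 <- grid$p > 0 & grid$N < 2L
  if (any(bad2)) grid <- grid[!bad2, , drop = FALSE]
  rownames(grid) <- NULL
  structure(list(puzzle = puzzle, grid = grid,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 max_trials = max_trials, move_kind = move_kind),
            class = "sweep_config")
}

#' Run a parameter sweep
#'
#' @param cfg a [sweep_config()] object.
#' @param verbose print one line per finished cell.
#' @return a tidy data.frame with one row per cell: `N`, `p`, `K`,
#'   `n_runs`, `mean_rescaled`, `std_rescaled`, `ratio_std_mean`, `sem`,
#'   `capped` (number of capped, hence excluded, runs).
#' @export
run_sweep <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  grid <- cfg$grid
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    res <- lapply(seq_len(cfg$replicates), function(ri) {
      run_search(cfg$puzzle,
                 search_params(N = grid$N[ci], p = grid$p[ci],
                               K = grid$K[ci],
                               seed = cfg$base_seed + 10000L * ci + ri,
                               max_trials = cfg$max_trials,
                               move_kind = cfg$move_kind))
    })
    s <- tryCatch(summarize_runs(res), error = function(e) NULL)
    if (is.null(s)) {  # (nearly) all runs hit the trial cap: report, not fail
      warning("cell N=", grid$N[ci], " p=", grid$p[ci], " K=", grid$K[ci],
              ": all runs capped")
      s <- list(n_used = 0L, mean_rescaled = NA_real_,
                std_rescaled = NA_real_, ratio_std_mean = NA_real_,
                sem_rescaled = NA_real_,
                capped_runs = sum(vapply(res, function(r) isTRUE(r$capped),
                                         logical(1L))))
    }
    rows[[ci]] <- data.frame(
      N = grid$N[ci], p = grid$p[ci], K = grid$K[ci], n_runs = s$n_used,
      mean_rescaled = s$mean_rescaled, std_rescaled = s$std_rescaled,
      ratio_std_mean = s$ratio_std_mean, sem = s$sem_rescaled,
      capped = s$capped_runs)
    if (verbose)
      cat(sprintf("cell %d/%d: N=%d p=%g K=%d mean=%.4g sem=%.2g\n",
                  ci, nrow(grid), grid$N[ci], grid$p[ci], grid$K[ci],
                  s$mean_rescaled, s$sem_rescaled))
  }
  do.call(rbind, rows)
}

#' Locate the optimal cooperation setting in a sweep table
#'
#' Returns the grid cell with the smallest mean rescaled cost and its
#' speed-up relative to the independent-search baseline (the mean over the
#' table's `p = 0` cells, weighted by run count).  If cooperation never
#' helps, the optimum is the baseline itself and the speed-up is 1.
#'
#' @param table a [run_sweep()] data.frame containing at least one
#'   `p = 0` row.
#' @return list with `N_opt`, `p_opt`, `K_opt`, `min_mean_cost`,
#'   `baseline_mean`, `speedup_vs_independent`.
#' @export
find_optimum <- function(table) {
  base <- table[table$p == 0, , drop = FALSE]
  if (nrow(base) == 0L) stop("table contains no p = 0 baseline cell")
  baseline <- sum(base$mean_rescaled * base$n_runs) / sum(base$n_runs)
  i <- which.min(table$mean_rescaled)
  list(N_opt = table$N[i], p_opt = table$p[i], K_opt = table$K[i],
       min_mean_cost = table$mean_rescaled[i], baseline_mean = baseline,
       speedup_vs_independent = baseline / table$mean_rescaled[i])
}

# per-figure default setups, scaled-down stand-ins for the published
# experiments (the original replicate counts are far beyond a desktop
# budget); every figure remains exactly reproducible from (id, scale, seed)
.figure_defaults <- list(
  fig1 = list(kind = "cost_dist", N = c(5L, 20L, 50L), p = 0, reps = 300L),
  fig2 = list(kind = "p_sweep", N = c(5L, 10L, 20L),
              p = c(0, 0.2, 0.4, 0.5, 0.6), reps = 100L),
  fig3 = list(kind = "cost_dist", N = 10L, p = 0.7, reps = 300L),
  fig4 = list(kind = "N_sweep", N = c(2L, 5L, 10L, 20L, 50L),
              p = c(0, 0.2, 0.5), reps = 60L),
  fig5 = list(kind = "stasis", N = c(20L, 100L), p = 0.5, reps = 15L),
  fig6 = list(kind = "p_sweep_K", N = 50L, K = c(3L, 10L, 25L, 49L),
              p = c(0, 0.2, 0.4, 0.5), reps = 60L),
  fig7 = list(kind = "K_sweep", N = 50L, K = c(1L, 2L, 5L, 10L, 25L, 49L),
              p = c(0.3, 0.5), reps = 60L),
  fig8 = list(kind = "p_sweep_puzzles", N = 20L,
              p = c(0, 0.2, 0.4, 0.5), reps = 60L,
              puzzle_seeds = c(101L, 102L, 103L, 104L)))

#' Reproduce one of the model's standard figures (reduced scale)
#'
#' Generates the data table (CSV) and a rendered plot (PDF) for one of the
#' eight standard experiments: cost distributions of the independent search
#' (fig1) and of a high-imitation system (fig3, with exponential tail
#' fit), the p-sweep (fig2), N-sweep (fig4) and K-sweeps (fig6, fig7) of
#' the mean cost, stasis distributions in the low- and high-cost regimes
#' (fig5), and the comparison of the alphametic with random ten-letter
#' puzzles (fig8).  Replicate counts are deliberately reduced; `scale`
#' shrinks them further (minimum 2 per cell).
#'
#' @param which `"fig1"` .. `"fig8"`.
#' @param scale replicate multiplier in (0, 1].
#' @param outdir output directory (created if needed).
#' @param seed base seed.
#' @param puzzle optional puzzle override (defaults to
#'   DONALD+GERALD=ROBERT); figure 8 generates its extra random puzzles
#'   internally.
#' @return invisibly, the list of written file paths.
#' @export
reproduce_figure <- function(which, scale = 1, outdir = ".", seed = 1L,
                             puzzle = NULL) {
  if (!which %in% names(.figure_defaults))
    stop("unknown figure id: ", which)
  cfg <- .figure_defaults[[which]]
  reps <- max(2L, as.integer(ceiling(cfg$reps * scale)))
  if (is.null(puzzle)) puzzle <- parse_puzzle("DONALD+GERALD=ROBERT")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(outdir, paste0(which, ".csv"))
  pdf_file <- file.path(outdir, paste0(which, ".pdf"))

  runs_for <- function(N, p, K, base_seed, pz = puzzle) {
    lapply(seq_len(reps), function(ri)
      run_search(pz, search_params(N = N, p = p, K = K,
                                   seed = base_seed + ri)))
  }

  if (cfg$kind == "cost_dist") {
    tabs <- list()
    for (i in seq_along(cfg$N)) {
      N <- cfg$N[i]
      res <- runs_for(N, cfg$p, max(N - 1L, 0L), seed + 10000L * i)
      h <- cost_histogram(res, breaks = 12, log_bins = TRUE)
      h$N <- N
      tabs[[i]] <- h
    }
    tab <- do.call(rbind, tabs)
    utils::write.csv(tab, csv, row.names = FALSE)
    grDevices::pdf(pdf_file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    mid <- (tab$bin_left + tab$bin_right) / 2
    keep <- tab$density > 0
    graphics::plot(mid[keep], tab$density[keep], log = "xy",
                   col = as.factor(tab$N[keep]), pch = 16,
                   xlab = "rescaled cost", ylab = "density",
                   main = paste0(which, ": cost distribution (p=", cfg$p, ")"))
    if (which == "fig3") {
      ft <- tryCatch(tail_fit(tab[tab$N == cfg$N[1L], ],
                              threshold = stats::median(mid)),
                     error = function(e) NULL)
      if (!is.null(ft))
        graphics::curve(ft["amplitude"] * exp(-ft["rate"] * x),
                        add = TRUE, col = "grey40")
    }
  } else if (cfg$kind %in% c("p_sweep", "N_sweep")) {
    sc <- sweep_config(puzzle, N = cfg$N, p = cfg$p, K = "full",
                       replicates = reps, base_seed = seed)
    tab <- run_sweep(sc)
    utils::write.csv(tab, csv, row.names = FALSE)
    grDevices::pdf(pdf_file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    if (cfg$kind == "p_sweep") {
      graphics::plot(tab$p, tab$mean_rescaled, log = "y", pch = 16,
                     col = as.factor(tab$N), xlab = "imitation probability p",
                     ylab = "mean rescaled cost", main = which)
    } else {
      graphics::plot(tab$N, tab$mean_rescaled, log = "xy", pch = 16,
                     col = as.factor(tab$p), xlab = "number of agents N",
                     ylab = "mean rescaled cost", main = which)
    }
  } else if (cfg$kind == "stasis") {
    tabs <- list()
    for (i in seq_along(cfg$N)) {
      N <- cfg$N[i]
      res <- runs_for(N, cfg$p, N - 1L, seed + 10000L * i)
      m <- vapply(res, function(r) r$stasis_M, numeric(1L))
      tabs[[i]] <- data.frame(N = N, stasis_M = m)
    }
    tab <- do.call(rbind, tabs)
    utils::write.csv(tab, csv, row.names = FALSE)
    grDevices::pdf(pdf_file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    graphics::boxplot(stasis_M ~ N, data = tab, log = "y",
                      xlab = "N", ylab = "stasis M", main = which)
  } else if (cfg$kind %in% c("p_sweep_K", "K_sweep")) {
    sc <- sweep_config(puzzle, N = cfg$N, p = cfg$p, K = cfg$K,
                       replicates = reps, base_seed = seed)
    tab <- run_sweep(sc)
    utils::write.csv(tab, csv, row.names = FALSE)
    grDevices::pdf(pdf_file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    xv <- if (cfg$kind == "K_sweep") tab$K else tab$p
    graphics::plot(xv, tab$mean_rescaled, log = "y", pch = 16,
                   col = as.factor(if (cfg$kind == "K_sweep") tab$p else tab$K),
                   xlab = if (cfg$kind == "K_sweep") "K" else "p",
                   ylab = "mean rescaled cost", main = which)
  } else {  # p_sweep_puzzles (fig8)
    puzzles <- c(list(puzzle),
                 lapply(cfg$puzzle_seeds, function(s)
                   random_puzzle(seed = s)))
    tabs <- list()
    for (i in seq_along(puzzles)) {
      sc <- sweep_config(puzzles[[i]], N = cfg$N, p = cfg$p, K = "full",
                         replicates = reps, base_seed = seed + 100000L * i)
      tab <- run_sweep(sc)
      tab$puzzle <- paste0(puzzles[[i]]$operand1, "+",
                           puzzles[[i]]$operand2, "=", puzzles[[i]]$result)
      tabs[[i]] <- tab
    }
    tab <- do.call(rbind, tabs)
    utils::write.csv(tab, csv, row.names = FALSE)
    grDevices::pdf(pdf_file, width = 6, height = 5)
    on.exit(grDevices::dev.off())
    graphics::plot(tab$p, tab$mean_rescaled, log = "y", pch = 16,
                   col = as.factor(tab$puzzle), xlab = "p",
                   ylab = "mean rescaled cost", main = which)
  }
  invisible(list(csv = csv, pdf = pdf_file))
}
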