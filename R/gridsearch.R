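#' Parameter grid specification
#'
#' The recommended two-dimensional search: `gamma` on a 0.2-spaced grid over
#' `[0, 1]` and `w_den` on an approximately logarithmic ladder
#' (3, 10, 30, 100, 300), each cell repeated with fresh random velocity and
#' restraint-selection seeds (5 to 20 repeats recommended).
#'
#' @param gammas numeric vector of deformation parameters in `[0, 1]`.
#' @param w_dens numeric vector of positive DEN weights.
#' @param repeats repeats per grid cell (>= 1).
#' @param base_seed integer; all cell seeds derive from it via
#'   [derive_seed()].
#' @return an object of class `den_grid_spec`.
#' @export
grid_spec <- function(gammas = seq(0, 1, by = 0.2),
                      w_dens = c(3, 10, 30, 100, 300),
                      repeats = 5, base_seed = 1) {
  if (any(gammas < 0 | gammas > 1)) stop("gammas must lie in [0, 1]")
  if (any(w_dens <= 0)) stop("w_dens must be positive")
  if (repeats < 1) stop("repeats must be >= 1")
  structure(list(gammas = gammas, w_dens = w_dens,
                 repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed)),
            class = "den_grid_spec")
}

#' @rdname grid_spec
#' @param w_den fixed weight for a line search over `gammas` only, keeping
#'   `w_den` constant (default 100).
#' @export
line_spec <- function(gammas = seq(0, 1, by = 0.2), w_den = 100,
                      repeats = 5, base_seed = 1) {
  grid_spec(gammas = gammas, w_dens = w_den, repeats = repeats,
            base_seed = base_seed)
}

#' Run the (gamma, w_DEN) grid search
#'
#' Executes one independent DEN refinement per grid cell and repeat. Each
#' repeat re-selects the restraint pairs and re-draws initial velocities
#' through a seed derived deterministically from
#' `derive_seed(base_seed, gamma_index, w_index, repeat)`, so the result table
#' is independent of execution order and reproducible. A failing cell is
#' recorded (with `NA` statistics and the error message) rather than aborting
#' the search.
#'
#' @param start,reference,refl,base_config as for [run_den_refinement()];
#'   the grid overrides `gamma`, `w_den` and `seed` of `base_config`.
#' @param grid a [grid_spec()].
#' @param truth optional known true structure; when given, each record also
#'   carries the refined model's RMSD to it (no superposition).
#' @return an object of class `den_grid_result` with `records` (one row per
#'   cell x repeat), `n_test`, and the list of refined `models`.
#' @export
run_grid <- function(start, reference, refl, base_config, grid, truth = NULL) {
  cells <- expand.grid(rep = seq_len(grid$repeats),
                       wi = seq_along(grid$w_dens),
                       gi = seq_along(grid$gammas))
  n <- nrow(cells)
  records <- data.frame(
    gamma = grid$gammas[cells$gi], w_den = grid$w_dens[cells$wi],
    rep = cells$rep, seed = NA_integer_,
    r_work = NA_real_, r_free = NA_real_, geometry_score = NA_real_,
    rmsd_to_truth = NA_real_, error = NA_character_,
    stringsAsFactors = FALSE
  )
  models <- vector("list", n)
  for (row in seq_len(n)) {
    seed <- derive_seed(grid$base_seed, cells$gi[row], cells$wi[row],
                        cells$rep[row])
    records$seed[row] <- seed
    cfg <- base_config
    cfg$gamma <- records$gamma[row]
    cfg$w_den <- records$w_den[row]
    cfg$seed <- seed
    res <- tryCatch(run_den_refinement(start, reference, refl, cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      records$error[row] <- conditionMessage(res)
      next
    }
    records$r_work[row] <- res$r_work
    records$r_free[row] <- res$r_free
    records$geometry_score[row] <- res$geometry_score
    if (!is.null(truth))
      records$rmsd_to_truth[row] <- rmsd_xyz(coords(res$model), coords(truth))
    models[[row]] <- res$model
  }
  n_test <- if (is.null(refl$is_test)) NA_integer_ else sum(refl$is_test)
  structure(list(records = records, n_test = n_test, models = models,
                 grid = grid),
            class = "den_grid_result")
}

#' R_free-based model selection with significance band and geometry tie-break
#'
#' An R_free difference is considered significant only when it exceeds twice
#' the estimated standard deviation \eqn{1/\sqrt{N_{test}}}. All records whose
#' R_free lies within \eqn{2/\sqrt{N_{test}}} of the minimum therefore form a
#' candidate set of statistically indistinguishable models, and the candidate
#' with the best (lowest) geometry score is selected.
#'
#' @param result a [run_grid()] result, or a plain data.frame of records with
#'   columns `r_free` and `geometry_score` (then `n_test` must be supplied).
#' @param n_test test-set size, required when `result` is a data.frame.
#' @return list with `selected` (one record row), `candidates` (the band),
#'   and `threshold` (`2 / sqrt(n_test)`).
#' @export
select_best <- function(result, n_test = NULL) {
  if (inherits(result, "den_grid_result")) {
    records <- result$records
    n_test <- result$n_test
  } else {
    records <- as.data.frame(result)
    if (is.null(n_test)) stop("n_test must be supplied with a raw record table")
  }
  ok <- which(!is.na(records$r_free))
  if (length(ok) == 0) stop("selection error: no successful refinement records")
  records <- records[ok, , drop = FALSE]
  threshold <- 2 / sqrt(n_test)
  band <- min(records$r_free) + threshold
  candidates <- records[records$r_free <= band, , drop = FALSE]
  selected <- candidates[which.min(candidates$geometry_score), , drop = FALSE]
  list(selected = selected, candidates = candidates, threshold = threshold)
}

#' Write grid records as a JSON-lines log
#'
#' One JSON object per refinement record (cell x repeat), suitable for
#' appending and streaming.
#'
#' @param result a [run_grid()] result.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_grid_jsonl <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (row in seq_len(nrow(result$records))) {
    writeLines(as.character(jsonlite::toJSON(
      as.list(result$records[row, ]), auto_unbox = TRUE, digits = NA,
      na = "null")), con)
  }
  invisible(path)
}

#' Export per-cell grid summaries for contour plotting
#'
#' Aggregates the record table to one CSV row per (gamma, w_den) cell: mean
#' and minimum R_free, mean RMSD to truth when available, and the number of
#' successful repeats actually used.
#'
#' @param result a [run_grid()] result.
#' @param path output CSV path.
#' @return invisibly, the aggregated data.frame.
#' @export
export_contours <- function(result, path) {
  rec <- result$records
  key <- interaction(rec$gamma, rec$w_den, drop = FALSE)
  agg <- do.call(rbind, lapply(split(rec, key), function(g) {
    ok <- !is.na(g$r_free)
    data.frame(gamma = g$gamma[1], w_den = g$w_den[1],
               mean_r_free = mean(g$r_free[ok]),
               min_r_free = suppressWarnings(min(g$r_free[ok])),
               mean_rmsd_to_truth = mean(g$rmsd_to_truth[ok]),
               n_repeats_used = sum(ok))
  }))
  agg <- agg[order(agg$gamma, agg$w_den), ]
  rownames(agg) <- NULL
  utils::write.csv(agg, path, row.names = FALSE)
  invisible(agg)
}
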